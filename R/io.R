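#' Write a cohort to plain-text files
#'
#' Serializes a cohort as per-subject matrix CSVs (n x n with node-id header
#' row and column, 0-based), a cohort manifest TSV (subject_id, group, age,
#' sex, batch, subgroup labels, path), a parcellation TSV and a truth-edge
#' TSV (node_i, node_j, signed effect).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_dir <- file.path(dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  node_ids <- cohort$parcellation$node_id
  paths <- character(length(cohort$matrices))
  for (i in seq_along(cohort$matrices)) {
    m <- cohort$matrices[[i]]
    dimnames(m) <- list(node_ids, node_ids)
    paths[i] <- file.path("matrices",
                          paste0(cohort$covariates$subject_id[i], ".csv"))
    write.csv(m, file.path(dir, paths[i]))
  }
  manifest <- cbind(cohort$covariates, path = paths)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(cohort$parcellation),
              file.path(dir, "parcellation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.tsv`, `parcellation.tsv`,
#'   per-subject matrix CSVs and (optionally) `truth_edges.tsv`.
#' @return A `synthetic_cohort`-shaped list (without a `spec`).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("no manifest.tsv under ", dir)
  manifest <- read.table(manifest_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  for (col in c("subject_id", "group", "path"))
    if (!col %in% names(manifest))
      stop("manifest is missing required column '", col, "'")
  parcellation <- read.table(file.path(dir, "parcellation.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  class(parcellation) <- c("parcellation", "data.frame")
  matrices <- lapply(manifest$path, function(p) {
    m <- as.matrix(read.csv(file.path(dir, p), row.names = 1,
                            check.names = FALSE))
    dimnames(m) <- NULL
    m
  })
  truth_path <- file.path(dir, "truth_edges.tsv")
  truth <- if (file.exists(truth_path)) {
    read.table(truth_path, sep = "\t", header = TRUE)
  } else {
    data.frame(node_i = integer(0), node_j = integer(0), effect = numeric(0))
  }
  covariates <- manifest[setdiff(names(manifest), "path")]
  covariates$group <- factor(covariates$group)
  if ("batch" %in% names(covariates))
    covariates$batch <- factor(covariates$batch)
  support <- Reduce(`|`, lapply(matrices, function(m) m != 0))
  out <- list(matrices = matrices, covariates = covariates, truth = truth,
              support = support, parcellation = parcellation, spec = NULL)
  class(out) <- "synthetic_cohort"
  out
}

# deterministic CSV writer for symmetric node x node matrices
write_matrix_csv <- function(m, path, node_ids) {
  dimnames(m) <- list(node_ids, node_ids)
  write.csv(m, path)
}
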