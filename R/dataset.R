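#' Vectorize connectivity matrices into an edge-by-subject dataset
#'
#' Retains the upper-triangle edges that are nonzero in at least
#' `min_prevalence` of subjects and stacks them into an edge-by-subject
#' value matrix. Edges are ordered lexicographically by (node_i, node_j).
#' Subjects with sparse, unstable connectomes are the usual reason some
#' edges fail the prevalence cut; with the default `min_prevalence = 1`
#' only edges present in every subject survive, so no zeros reach the
#' subsequent log transform.
#'
#' @param cohort a `synthetic_cohort`, or a list with elements `matrices`,
#'   `covariates`, `parcellation`.
#' @param min_prevalence required fraction of subjects with a nonzero value,
#'   in \[0, 1\].
#' @return A list of class `cohort_dataset`: `Y` (edges x subjects, natural
#'   scale), `edges` (data.frame `node_i`, `node_j`, 0-based, i < j),
#'   `covariates`, `parcellation`, `scale` (`"natural"`).
#' @export
filter_edges <- function(cohort, min_prevalence = 1) {
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("min_prevalence must be in [0, 1]")
  matrices <- cohort$matrices
  if (is.null(matrices) || !length(matrices))
    stop("cohort has no matrices")
  n_nodes <- nrow(matrices[[1L]])
  if (!all(vapply(matrices, function(m) all(dim(m) == n_nodes), logical(1))))
    stop("all matrices must share the same node count")

  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  vals <- vapply(matrices, function(m) m[pairs], numeric(nrow(pairs)))
  prevalence <- rowMeans(vals != 0)
  keep <- prevalence >= min_prevalence & prevalence > 0
  if (!any(keep))
    stop("no edges meet min_prevalence = ", min_prevalence,
         "; the retained edge set is empty")

  Y <- vals[keep, , drop = FALSE]
  edges <- data.frame(node_i = unname(pairs[keep, 1L]) - 1L,
                      node_j = unname(pairs[keep, 2L]) - 1L)
  rownames(edges) <- NULL
  rownames(Y) <- paste0(edges$node_i, "-", edges$node_j)
  colnames(Y) <- cohort$covariates$subject_id

  out <- list(Y = Y, edges = edges, covariates = cohort$covariates,
              parcellation = cohort$parcellation, scale = "natural")
  class(out) <- "cohort_dataset"
  out
}

#' Log-transform edge values
#'
#' Structural connectome edge weights are approximately log-normal; the
#' harmonization and GLM stages operate on the log scale. Exact zeros inside
#' the retained support are only admissible with an explicit positive
#' `offset` (added to the zeros alone).
#'
#' @param dataset a `cohort_dataset` on the natural scale.
#' @param offset optional positive value added to exact zeros before logging.
#' @return The dataset with `Y = log(Y)` and `scale = "log"`.
#' @export
log_transform <- function(dataset, offset = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!identical(dataset$scale, "natural"))
    stop("dataset is already on the ", dataset$scale, " scale")
  Y <- dataset$Y
  if (any(Y < 0)) stop("negative edge values cannot be log-transformed")
  zeros <- Y == 0
  if (any(zeros)) {
    if (is.null(offset))
      stop("zero edge values present; supply a positive offset or filter ",
           "with min_prevalence = 1")
    if (offset <= 0) stop("offset must be > 0")
    Y[zeros] <- offset
  }
  dataset$Y <- log(Y)
  dataset$scale <- "log"
  dataset
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", nrow(x$Y), "edges x", ncol(x$Y),
      "subjects (", x$scale, "scale )\n")
  invisible(x)
}

# symmetric matrix from an upper-triangle edge vector
edge_vector_to_matrix <- function(values, edges, n_nodes) {
  m <- matrix(0, n_nodes, n_nodes)
  ij <- cbind(edges$node_i + 1L, edges$node_j + 1L)
  m[ij] <- values
  m[ij[, c(2L, 1L), drop = FALSE]] <- values
  m
}

# upper-triangle edge vector from a symmetric matrix
matrix_to_edge_vector <- function(m, edges) {
  m[cbind(edges$node_i + 1L, edges$node_j + 1L)]
}
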