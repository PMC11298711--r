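#' Configuration for a full TFNBS pipeline run
#'
#' Defaults mirror the analysis design the package emulates: 5000
#' permutations, alpha = .05, age and sex as nuisance covariates,
#' Freedman-Lane permutation, both directionalities reported.
#'
#' @param seed integer seed driving the permutation engine.
#' @param min_prevalence edge prevalence filter (see [filter_edges()]).
#' @param harmonize logical; fit and apply batch harmonization.
#' @param batch_column batch column name.
#' @param combat_tol,combat_max_iter convergence controls for
#'   [fit_combat()].
#' @param group_column,contrast grouping column and
#'   `c(level_tested, level_reference)`.
#' @param nuisance nuisance covariate columns.
#' @param directions subset of `c("decrease", "increase")`; "decrease"
#'   tests where the tested level has lower values than the reference.
#' @param E,H,n_steps,P,scheme,h_max_policy enhancement and permutation
#'   parameters (see [permutation_pvalues()]).
#' @param alpha significance level in (0, 1).
#' @param correction `"corrected"` or `"uncorrected"` for the reported
#'   summaries.
#' @param top_k number of top connections to extract.
#' @param log_offset optional offset for zeros in [log_transform()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, min_prevalence = 1, harmonize = TRUE,
                       batch_column = "batch", combat_tol = 1e-4,
                       combat_max_iter = 100L,
                       group_column = "group", contrast = c("TLE", "HC"),
                       nuisance = c("age", "sex"),
                       directions = c("decrease", "increase"),
                       E = 0.5, H = 2.25, n_steps = 100L, P = 5000L,
                       scheme = "freedman_lane",
                       h_max_policy = "permutation", alpha = 0.05,
                       correction = "corrected", top_k = 16L,
                       log_offset = NULL) {
  if (P < 1) stop("P must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  directions <- match.arg(directions, c("decrease", "increase"),
                          several.ok = TRUE)
  correction <- match.arg(correction, c("corrected", "uncorrected"))
  cfg <- list(seed = as.integer(seed), min_prevalence = min_prevalence,
              harmonize = isTRUE(harmonize), batch_column = batch_column,
              combat_tol = combat_tol,
              combat_max_iter = as.integer(combat_max_iter),
              group_column = group_column, contrast = contrast,
              nuisance = nuisance, directions = directions,
              E = E, H = H, n_steps = as.integer(n_steps),
              P = as.integer(P), scheme = scheme,
              h_max_policy = h_max_policy, alpha = alpha,
              correction = correction, top_k = as.integer(top_k),
              log_offset = log_offset)
  class(cfg) <- "run_config"
  cfg
}

pipeline_stage <- function(name, expr, quiet) {
  if (!quiet) message("[tfnbs] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full simulate/harmonize/GLM/TFNBS/summarize pipeline
#'
#' Orchestrates filter -> log-transform -> harmonization -> edge GLM ->
#' threshold-free enhancement with permutation inference -> lobe-pair
#' summaries, writing every stage output and the run metadata under
#' `out_dir`. Deterministic given the config seed: rerunning an identical
#' config yields byte-identical output files.
#'
#' @param cohort a `synthetic_cohort` (or any list with `matrices`,
#'   `covariates`, `parcellation`), or a directory readable by
#'   [read_cohort()].
#' @param config a [run_config()].
#' @param out_dir output directory; created if missing. `NULL` skips
#'   writing.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the harmonized `dataset`, per-direction
#'   `pvalues`, `summaries`, `top`, `adjusted`, the `model` (if
#'   harmonized), and `config`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  for (col in c(config$group_column, config$nuisance,
                if (config$harmonize) config$batch_column))
    if (!col %in% names(cohort$covariates))
      stop("manifest/covariates are missing required column '", col, "'")

  dataset <- pipeline_stage("filter_edges",
    filter_edges(cohort, config$min_prevalence), quiet)
  dataset <- pipeline_stage("log_transform",
    log_transform(dataset, offset = config$log_offset), quiet)

  model <- NULL
  if (config$harmonize) {
    model <- pipeline_stage("fit_combat",
      fit_combat(dataset, batch = config$batch_column,
                 preserve = c(config$group_column, config$nuisance),
                 tol = config$combat_tol,
                 max_iter = config$combat_max_iter), quiet)
    dataset <- pipeline_stage("apply_combat",
      apply_combat(model, dataset), quiet)
  }

  design <- pipeline_stage("build_design",
    build_design(dataset$covariates, config$group_column, config$contrast,
                 config$nuisance), quiet)

  dir_sign <- c(decrease = -1L, increase = 1L)
  pvalues <- list(); summaries <- list(); top <- list(); adjusted <- list()
  for (d in config$directions) {
    pv <- pipeline_stage(paste0("permutation_pvalues[", d, "]"),
      permutation_pvalues(dataset, design, E = config$E, H = config$H,
                          n_steps = config$n_steps, P = config$P,
                          seed = config$seed, scheme = config$scheme,
                          direction = dir_sign[[d]],
                          h_max_policy = config$h_max_policy), quiet)
    sig <- significant_edges(pv, config$alpha, config$correction)
    summaries[[d]] <- lobe_pair_summary(sig$mask, dataset$parcellation,
                                        direction = d,
                                        correction = config$correction)
    top[[d]] <- suppressMessages(
      top_connections(pv, dataset$parcellation, config$top_k, config$alpha))
    adjusted[[d]] <- if (nrow(top[[d]])) {
      extract_adjusted(dataset, top[[d]], design)
    } else NULL
    pvalues[[d]] <- pv
  }

  result <- list(dataset = dataset, model = model, design = design,
                 pvalues = pvalues, summaries = summaries, top = top,
                 adjusted = adjusted, config = config)

  if (!is.null(out_dir)) {
    pipeline_stage("write_outputs",
                   write_run_outputs(result, out_dir), quiet)
  }
  invisible(result)
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  node_ids <- result$dataset$parcellation$node_id
  first <- result$pvalues[[1L]]
  write_matrix_csv(first$t, file.path(out_dir, "stat_t.csv"), node_ids)
  for (d in names(result$pvalues)) {
    pv <- result$pvalues[[d]]
    ddir <- file.path(out_dir, paste0("direction-", d))
    dir.create(ddir, showWarnings = FALSE)
    write_matrix_csv(pv$score, file.path(ddir, "score.csv"), node_ids)
    write_matrix_csv(pv$p_corrected,
                     file.path(ddir, "p_corrected.csv"), node_ids)
    write_matrix_csv(pv$p_uncorrected,
                     file.path(ddir, "p_uncorrected.csv"), node_ids)
    write.table(data.frame(null_max = pv$null_max),
                file.path(ddir, "null_max.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.csv(result$summaries[[d]], file.path(ddir, "lobe_pairs.csv"),
              row.names = FALSE)
    write.csv(result$top[[d]], file.path(ddir, "top_connections.csv"),
              row.names = FALSE)
    if (!is.null(result$adjusted[[d]]))
      write.table(result$adjusted[[d]],
                  file.path(ddir, "adjusted_values.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- result$config
  meta <- list(
    package = "tfnbs",
    version = as.character(utils::packageVersion("tfnbs")),
    config = cfg[setdiff(names(cfg), NULL)],
    n_subjects = ncol(result$dataset$Y),
    n_edges = nrow(result$dataset$Y),
    harmonized = !is.null(result$model),
    dof = result$design$dof
  )
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' Run the pipeline on a subgroup contrast
#'
#' Subsets the cohort to subjects whose `subgroup_column` value is one of
#' `levels`, then runs the identical downstream pipeline with
#' `subgroup_column` as the grouping variable — e.g. seizure-history
#' positive vs negative patients, or an impairment cluster vs controls.
#'
#' @param cohort as in [run_pipeline()].
#' @param config a [run_config()]; its `group_column`/`contrast` are
#'   replaced by the subgroup choice.
#' @param subgroup_column covariate column defining the subgroup labels.
#' @param levels `c(level_tested, level_reference)`; both must have >= 2
#'   subjects.
#' @param out_dir,quiet as in [run_pipeline()].
#' @return As [run_pipeline()].
#' @export
subgroup_run <- function(cohort, config, subgroup_column, levels,
                         out_dir = NULL, quiet = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!subgroup_column %in% names(cohort$covariates))
    stop("no subgroup column '", subgroup_column, "'")
  lab <- as.character(cohort$covariates[[subgroup_column]])
  if (length(levels) != 2L) stop("levels must name exactly two labels")
  counts <- table(lab[lab %in% levels])
  missing_lv <- setdiff(levels, names(counts))
  if (length(missing_lv))
    stop("subgroup level(s) absent: ", paste(missing_lv, collapse = ", "))
  if (any(counts < 2L))
    stop("each subgroup level needs at least 2 subjects")

  keep <- which(lab %in% levels)
  sub <- cohort
  sub$matrices <- cohort$matrices[keep]
  sub$covariates <- cohort$covariates[keep, , drop = FALSE]
  config$group_column <- subgroup_column
  config$contrast <- levels
  run_pipeline(sub, config, out_dir = out_dir, quiet = quiet)
}
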