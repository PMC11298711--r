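#' Build a design matrix for an edge-wise group contrast
#'
#' Constructs the GLM design for a two-level group comparison with nuisance
#' covariates (age and sex by default; age is centered at the sample mean).
#' Subjects whose group label is missing or outside the two contrasted
#' levels are dropped (with a message), which is how subgroup analyses
#' (e.g. seizure-history or cognitive-impairment strata) reuse the same
#' machinery via an alternative `group_column`.
#'
#' @param covariates data.frame with one row per subject.
#' @param group_column name of the grouping column.
#' @param contrast_spec character vector `c(level_tested, level_reference)`;
#'   the contrast estimates `level_tested - level_reference`.
#' @param nuisance names of nuisance covariate columns (numeric or 0/1).
#' @return A list of class `design_matrix`: `X` (subjects x columns,
#'   intercept / group indicator / centered nuisance), `contrast`, `keep`
#'   (row indices of `covariates` used), `group_column`, `levels`, `dof`.
#' @examples
#' cov <- data.frame(group = rep(c("HC", "TLE"), each = 4),
#'                   age = 20:27, sex = rep(0:1, 4))
#' d <- build_design(cov, "group", c("TLE", "HC"))
#' d$contrast
#' @export
build_design <- function(covariates, group_column = "group",
                         contrast_spec = NULL,
                         nuisance = c("age", "sex")) {
  if (!group_column %in% names(covariates))
    stop("no column '", group_column, "' in covariates")
  g_raw <- as.character(covariates[[group_column]])
  levels_present <- unique(g_raw[!is.na(g_raw)])
  if (is.null(contrast_spec)) {
    if (length(levels_present) != 2L)
      stop("group column '", group_column, "' has ",
           length(levels_present), " levels; supply contrast_spec")
    contrast_spec <- rev(sort(levels_present))
  }
  if (length(contrast_spec) != 2L)
    stop("contrast_spec must name exactly two levels")
  absent <- setdiff(contrast_spec, levels_present)
  if (length(absent))
    stop("level(s) not present in '", group_column, "': ",
         paste(absent, collapse = ", "))

  keep <- which(g_raw %in% contrast_spec)
  missing_cov <- setdiff(nuisance, names(covariates))
  if (length(missing_cov))
    stop("nuisance columns not in covariates: ",
         paste(missing_cov, collapse = ", "))
  if (length(nuisance)) {
    ok <- stats::complete.cases(covariates[keep, nuisance, drop = FALSE])
    keep <- keep[ok]
  }
  n_drop <- nrow(covariates) - length(keep)
  if (n_drop > 0)
    message("build_design: dropped ", n_drop,
            " subject(s) outside levels {",
            paste(contrast_spec, collapse = ", "), "} of '",
            group_column, "'")

  g <- g_raw[keep]
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L))
    stop("each contrasted level needs at least 2 subjects")

  ind <- as.numeric(g == contrast_spec[1L]) # tested level indicator
  X <- cbind(`(Intercept)` = 1, ind)
  colnames(X)[2L] <- paste0(group_column, contrast_spec[1L])
  for (nc in nuisance) {
    v <- as.numeric(covariates[[nc]][keep])
    if (nc == "age") v <- v - mean(v) # centered for a stable intercept
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- nc
  }
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X))
    stop("design matrix is rank deficient (collinear covariates?)")

  contrast <- c(0, 1, rep(0, length(nuisance)))
  out <- list(X = X, contrast = contrast, keep = keep,
              group_column = group_column, levels = contrast_spec,
              nuisance = nuisance, dof = nrow(X) - ncol(X))
  class(out) <- "design_matrix"
  out
}

#' Edge-wise GLM t-statistic graph
#'
#' Fits, per retained edge, an ordinary least squares model of the edge
#' value on the design and returns the contrast t-statistics
#' \eqn{t = c^\top\hat\beta / \sqrt{\hat\sigma^2 c^\top (X^\top X)^{-1} c}}
#' assembled into a symmetric statistic graph. Edges with (numerically)
#' zero residual variance get `+/- t_cap` with a warning so downstream
#' enhancement stays finite.
#'
#' @param dataset a `cohort_dataset` (log scale recommended).
#' @param design a [build_design()] result built from
#'   `dataset$covariates`.
#' @param t_cap cap on `|t|` for degenerate edges.
#' @return A list of class `stat_graph`: `t` (symmetric n x n matrix, zero
#'   off-support), `dof`, `direction` (+1), `edges`, `design`.
#' @export
edge_tstats <- function(dataset, design, t_cap = 1e6) {
  stopifnot(inherits(dataset, "cohort_dataset"),
            inherits(design, "design_matrix"))
  X <- design$X
  Y <- dataset$Y[, design$keep, drop = FALSE]
  if (ncol(Y) != nrow(X))
    stop("design rows do not match dataset subjects")

  tv <- glm_contrast_t(Y, X, design$contrast, t_cap)
  n_nodes <- nrow(dataset$parcellation)
  out <- list(t = edge_vector_to_matrix(tv, dataset$edges, n_nodes),
              dof = design$dof, direction = 1L,
              edges = dataset$edges, design = design)
  class(out) <- "stat_graph"
  out
}

# vectorized per-edge OLS contrast t; Y is edges x subjects
glm_contrast_t <- function(Y, X, contrast, t_cap = 1e6) {
  qr_X <- qr(X)
  XtXinv <- chol2inv(qr.R(qr_X))
  w <- X %*% XtXinv %*% contrast
  cXXc <- drop(t(contrast) %*% XtXinv %*% contrast)
  Qm <- qr.Q(qr_X)
  dof <- nrow(X) - qr_X$rank
  bc <- drop(Y %*% w)
  rss <- pmax(rowSums(Y^2) - rowSums((Y %*% Qm)^2), 0)
  sigma2 <- rss / dof
  denom <- sqrt(sigma2 * cXXc)
  tv <- ifelse(denom > 0, bc / denom, sign(bc) * t_cap)
  if (any(abs(tv) > t_cap)) {
    warning("capping ", sum(abs(tv) > t_cap),
            " degenerate t-statistic(s) at ", t_cap)
    tv <- pmin(pmax(tv, -t_cap), t_cap)
  }
  tv
}

#' @export
print.stat_graph <- function(x, ...) {
  tv <- x$t[cbind(x$edges$node_i + 1L, x$edges$node_j + 1L)]
  cat("stat_graph:", length(tv), "edges, dof =", x$dof,
      "| t range [", signif(min(tv), 4), ",", signif(max(tv), 4), "]\n")
  invisible(x)
}

#' Nuisance-adjusted edge values
#'
#' Removes the estimated nuisance (e.g. age and sex) contribution from each
#' edge value while keeping the group effect: the full model (group +
#' nuisance) is fitted and only the centered-nuisance part subtracted, so
#' the grand mean is retained and the group-mean difference of adjusted
#' values equals the GLM group effect. This is the quantity shown in
#' adjusted-value box plots for representative connections.
#'
#' @param dataset a `cohort_dataset`.
#' @param design a [build_design()] result (its `nuisance` columns are
#'   removed).
#' @return Matrix of adjusted values (edges x retained subjects).
#' @export
residualize_adjusted <- function(dataset, design) {
  stopifnot(inherits(dataset, "cohort_dataset"),
            inherits(design, "design_matrix"))
  X <- design$X
  Y <- dataset$Y[, design$keep, drop = FALSE]
  nuis_cols <- which(colnames(X) %in% design$nuisance)
  if (!length(nuis_cols)) return(Y)
  qr_X <- qr(X)
  beta <- qr.coef(qr_X, t(Y))              # p x E
  N <- scale(X[, nuis_cols, drop = FALSE], center = TRUE, scale = FALSE)
  Y - t(N %*% beta[nuis_cols, , drop = FALSE])
}
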