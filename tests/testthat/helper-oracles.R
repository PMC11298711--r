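# Independent oracles used across the suite. These deliberately avoid the
# package's union-find / C++ paths: components via a plain R union-find,
# TFCE via a naive threshold loop, GLM via per-edge lm().

# union-find membership of edges (matrix with 0-based node columns)
uf_edge_components <- function(edges_mat, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(edges_mat))) {
    ri <- find(edges_mat[r, 1L] + 1L)
    rj <- find(edges_mat[r, 2L] + 1L)
    if (ri != rj) parent[rj] <- ri
  }
  # label edges by the root of their first endpoint
  roots <- vapply(seq_len(n_nodes), find, numeric(1))
  roots[edges_mat[, 1L] + 1L]
}

# naive TFCE: explicit loop over thresholds, components recomputed per
# threshold from scratch
naive_tfce <- function(tvec, edges, n_nodes, E, H, K, h_max = max(tvec, 0)) {
  score <- numeric(length(tvec))
  if (h_max <= 0) return(score)
  dh <- h_max / K
  for (k in seq_len(K)) {
    h <- k * dh
    supra <- which(tvec > h)
    if (!length(supra)) next
    em <- cbind(edges$node_i[supra], edges$node_j[supra])
    memb <- uf_edge_components(em, n_nodes)
    ext <- table(memb)
    score[supra] <- score[supra] +
      as.numeric(ext[as.character(memb)])^E * h^H * dh
  }
  score
}

# per-edge regression oracle via lm()
lm_contrast_t <- function(y, X, contrast) {
  df <- as.data.frame(X[, -1, drop = FALSE])
  names(df) <- paste0("v", seq_along(df))
  fit <- lm(y ~ ., data = df)
  b <- coef(fit)
  V <- vcov(fit)
  drop(contrast %*% b) / sqrt(drop(t(contrast) %*% V %*% contrast))
}

# build a cohort_dataset directly from an edge-by-subject value matrix
toy_dataset <- function(Y, edges, covariates, n_nodes = max(edges) + 1L,
                        scale = "log") {
  parc <- make_parcellation(max(n_nodes, 2L), "uniform")
  rownames(Y) <- paste0(edges$node_i, "-", edges$node_j)
  out <- list(Y = Y, edges = edges, covariates = covariates,
              parcellation = parc, scale = scale)
  class(out) <- "cohort_dataset"
  out
}

# a stat_graph from a plain vector of edge statistics
toy_stat_graph <- function(tvec, edges, n_nodes) {
  m <- matrix(0, n_nodes, n_nodes)
  ij <- cbind(edges$node_i + 1L, edges$node_j + 1L)
  m[ij] <- tvec
  m[ij[, c(2L, 1L), drop = FALSE]] <- tvec
  out <- list(t = m, dof = NA_integer_, direction = 1L, edges = edges)
  class(out) <- "stat_graph"
  out
}

# random sparse statistic graph for property tests
random_stat_graph <- function(n_nodes, density = 0.5, t_sd = 2) {
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  keep <- which(runif(nrow(pairs)) < density)
  if (!length(keep)) keep <- sample(nrow(pairs), 1L)
  edges <- data.frame(node_i = pairs[keep, 1L] - 1L,
                      node_j = pairs[keep, 2L] - 1L)
  tvec <- rnorm(length(keep), sd = t_sd)
  list(graph = toy_stat_graph(tvec, edges, n_nodes),
       tvec = tvec, edges = edges, n_nodes = n_nodes)
}

# quick null cohort used by calibration-style tests
null_cohort <- function(seed, n_per_group = 30, n_nodes = 20) {
  spec <- cohort_spec(n_group_a = n_per_group, n_group_b = n_per_group,
                      n_nodes = n_nodes, edge_density = 0.3,
                      effect_size = 0, planted_edge_fraction = 0,
                      batch_shift = 0, batch_scale = 1, seed = seed)
  simulate_cohort(spec, make_parcellation(n_nodes, "uniform"))
}
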