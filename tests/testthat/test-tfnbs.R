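test_that("suprathreshold components match connectivity by shared nodes", {
  # path 0-1-2-3, all t = 2: one component of extent 3 at h = 1
  edges <- data.frame(node_i = 0:2, node_j = 1:3)
  sg <- toy_stat_graph(rep(2, 3), edges, 4)
  comps <- components_at_threshold(sg, 1)
  expect_length(comps, 1)
  expect_equal(nrow(comps[[1]]), 3)

  # two disjoint suprathreshold edges: two components of extent 1
  edges2 <- data.frame(node_i = c(0L, 2L), node_j = c(1L, 3L))
  comps2 <- components_at_threshold(toy_stat_graph(c(2, 3), edges2, 4), 1)
  expect_length(comps2, 2)
  expect_true(all(vapply(comps2, nrow, integer(1)) == 1))

  # nothing above threshold
  expect_length(components_at_threshold(sg, 5), 0)
  expect_error(components_at_threshold(sg, 0), "> 0")
})

test_that("component partitions agree with a union-find oracle", {
  set.seed(401)
  for (rep in 1:20) {
    rg <- random_stat_graph(5, density = 0.6)
    h <- runif(1, 0.1, 2)
    comps <- components_at_threshold(rg$graph, h)
    supra <- which(rg$tvec > h)
    if (!length(supra)) {
      expect_length(comps, 0)
      next
    }
    memb <- uf_edge_components(
      cbind(rg$edges$node_i[supra], rg$edges$node_j[supra]), 5)
    expect_length(comps, length(unique(memb)))
    # same multiset of component extents
    expect_equal(sort(vapply(comps, nrow, integer(1))),
                 sort(as.numeric(table(memb))), ignore_attr = TRUE)
  }
})

test_that("enhancement of an isolated edge approaches the analytic integral", {
  edges <- data.frame(node_i = 0L, node_j = 1L)
  sg <- toy_stat_graph(2, edges, 2)
  for (E in c(0, 0.5, 2)) {
    eg <- tfce_enhance(sg, E = E, H = 2, n_steps = 1000)
    expect_lt(abs(eg$score[1, 2] - 8 / 3) / (8 / 3), 0.01)
  }
  # all-nonpositive statistics enhance to zero without error
  sg_neg <- toy_stat_graph(c(-1), edges, 2)
  expect_true(all(tfce_enhance(sg_neg)$score == 0))
})

test_that("enhanced scores equal the naive threshold-loop oracle", {
  set.seed(411)
  for (rep in 1:20) {
    n_nodes <- sample(4:8, 1)
    rg <- random_stat_graph(n_nodes, density = 0.5)
    eg <- tfce_enhance(rg$graph, E = 0.5, H = 2.25, n_steps = 50)
    oracle <- naive_tfce(rg$tvec, rg$edges, n_nodes, 0.5, 2.25, 50)
    got <- eg$score[cbind(rg$edges$node_i + 1, rg$edges$node_j + 1)]
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("enhancement is monotone in the statistic heights", {
  set.seed(421)
  rg <- random_stat_graph(8, density = 0.5)
  e1 <- tfce_enhance(rg$graph, H = 2.25)
  scaled <- toy_stat_graph(rg$tvec * 1.5, rg$edges, 8)
  e2 <- tfce_enhance(scaled, H = 2.25)
  pos <- e1$score > 0
  expect_true(any(pos))
  expect_true(all(e2$score[pos] > e1$score[pos]))
})

perm_setup <- function(seed = 431, n_per_group = 12, n_nodes = 10) {
  co <- null_cohort(seed, n_per_group, n_nodes)
  ds <- log_transform(filter_edges(co))
  d <- build_design(ds$covariates, "group", c("TLE", "HC"))
  list(ds = ds, d = d)
}

test_that("p-value graphs obey the estimator bounds and orderings", {
  s <- perm_setup()
  pg <- permutation_pvalues(s$ds, s$d, P = 50, seed = 1)
  ij <- cbind(pg$edges$node_i + 1, pg$edges$node_j + 1)
  expect_true(all(pg$p_uncorrected[ij] >= 1 / 51))
  expect_true(all(pg$p_corrected[ij] <= 1))
  expect_true(all(pg$p_corrected[ij] >= pg$p_uncorrected[ij]))
  expect_length(pg$null_max, 50)
  expect_true(all(pg$null_max >= 0))

  # identical seed reproduces exactly; different seed does not
  pg2 <- permutation_pvalues(s$ds, s$d, P = 50, seed = 1)
  expect_identical(pg, pg2)
  pg3 <- permutation_pvalues(s$ds, s$d, P = 50, seed = 2)
  expect_false(identical(pg$null_max, pg3$null_max))
})

test_that("engine t-statistics equal edge_tstats on the observed data", {
  s <- perm_setup(seed = 441)
  pg <- permutation_pvalues(s$ds, s$d, P = 5, seed = 1)
  sg <- edge_tstats(s$ds, s$d)
  expect_equal(pg$t, sg$t, tolerance = 1e-10)
})

test_that("tiny cohorts fall back to exhaustive enumeration", {
  cov <- data.frame(subject_id = paste0("S", 1:6),
                    group = rep(c("A", "B"), each = 3))
  edges <- data.frame(node_i = 0L, node_j = 1L)
  set.seed(451)
  ds <- toy_dataset(matrix(rnorm(6, mean = rep(c(0, 2), each = 3)), 1),
                    edges, cov, 2)
  d <- build_design(cov, "group", c("B", "A"), nuisance = character(0))
  expect_warning(
    pg <- permutation_pvalues(ds, d, P = 1000, scheme = "simple_label",
                              seed = 1, direction = 1),
    "exhaustive")
  expect_equal(pg$P, 20)
  expect_true(pg$params$exhaustive)

  # independent oracle: enumerate all 20 assignments by hand
  y <- ds$Y[1, ]
  obs_t <- (mean(y[4:6]) - mean(y[1:3])) /
    sqrt(sum((y[4:6] - mean(y[4:6]))^2 + (y[1:3] - mean(y[1:3]))^2) / 4 *
           (2 / 3))
  sets <- combn(6, 3)
  null_t <- apply(sets, 2, function(s1) {
    a <- y[s1]; b <- y[-s1] # a = subjects relabelled as the tested group
    sp <- sum((a - mean(a))^2 + (b - mean(b))^2) / 4
    (mean(a) - mean(b)) / sqrt(sp * 2 / 3)
  })
  # single edge: each graph is enhanced over its own ladder (default policy)
  obs_score <- naive_tfce(obs_t, edges, 2, 0.5, 2.25, 100, h_max = obs_t)
  null_score <- vapply(null_t, function(tt)
    naive_tfce(tt, edges, 2, 0.5, 2.25, 100, h_max = max(tt, 0)),
    numeric(1))
  p_oracle <- (1 + sum(null_score >= obs_score)) / 21
  expect_equal(pg$p_uncorrected[1, 2], p_oracle)
  expect_equal(pg$p_corrected[1, 2], p_oracle)
})

test_that("null uncorrected p-values are tail-calibrated (sub-uniform)", {
  # one-sided enhanced scores put an atom at p = 1 (edges with t <= 0 in the
  # tested direction score zero), so the correct null property is validity of
  # the tails, not strict uniformity: P(p <= alpha) stays at or just below
  # alpha for small alpha.
  rej05 <- rej20 <- numeric(60)
  for (i in 1:60) {
    co <- null_cohort(seed = 20000 + i)
    ds <- log_transform(filter_edges(co))
    d <- build_design(ds$covariates, "group", c("TLE", "HC"))
    pg <- permutation_pvalues(ds, d, P = 200, seed = i, direction = -1)
    ij <- cbind(pg$edges$node_i + 1, pg$edges$node_j + 1)
    p <- pg$p_uncorrected[ij]
    rej05[i] <- mean(p <= 0.05)
    rej20[i] <- mean(p <= 0.2)
  }
  expect_gt(mean(rej05), 0.03)
  expect_lt(mean(rej05), 0.08)
  expect_gt(mean(rej20), 0.15)
  expect_lt(mean(rej20), 0.25)
})
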