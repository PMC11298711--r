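make_two_batch_dataset <- function(seed = 101, n_per_group = 100,
                                   shift = c(0, 1), scale = c(1, 1.5)) {
  p <- make_parcellation(12, "uniform")
  spec <- cohort_spec(n_group_a = n_per_group, n_group_b = n_per_group,
                      n_nodes = 12, edge_density = 0.75, effect_size = 1,
                      planted_edge_fraction = 0.3,
                      batch_shift = shift, batch_scale = scale, seed = seed)
  co <- simulate_cohort(spec, p)
  log_transform(filter_edges(co))
}

test_that("edge prevalence filtering matches hand counts on a toy cohort", {
  # 4 nodes; edge (0,1) in all subjects, (0,2) in 2/4, (2,3) in 1/4
  base <- matrix(0, 4, 4)
  put <- function(m, i, j, v) { m[i + 1, j + 1] <- v; m[j + 1, i + 1] <- v; m }
  m1 <- put(put(put(base, 0, 1, 1), 0, 2, 2), 2, 3, 3)
  m2 <- put(put(base, 0, 1, 1), 0, 2, 2)
  m3 <- put(base, 0, 1, 2)
  m4 <- put(base, 0, 1, 5)
  cohort <- list(matrices = list(m1, m2, m3, m4),
                 covariates = data.frame(subject_id = paste0("S", 1:4)),
                 parcellation = make_parcellation(4, "uniform"))

  full <- filter_edges(cohort, min_prevalence = 1)
  expect_equal(full$edges, data.frame(node_i = 0L, node_j = 1L))

  half <- filter_edges(cohort, min_prevalence = 0.5)
  expect_equal(nrow(half$Y), 2) # (0,1) and (0,2); (2,3) at 25% dropped
  expect_equal(half$edges$node_j, c(1L, 2L))

  any_edge <- filter_edges(cohort, min_prevalence = 0)
  expect_equal(nrow(any_edge$Y), 3)

  empty <- list(matrices = list(base, base),
                covariates = data.frame(subject_id = c("a", "b")),
                parcellation = make_parcellation(4, "uniform"))
  expect_error(filter_edges(empty, 1), "empty")
})

test_that("log transform is exact, invertible, and guards zeros", {
  edges <- data.frame(node_i = 0L, node_j = 1L)
  cov <- data.frame(subject_id = c("a", "b", "c"))
  ds <- toy_dataset(matrix(c(1, exp(2), 5), 1), edges, cov, 2,
                    scale = "natural")
  out <- log_transform(ds)
  expect_equal(unname(out$Y[1, 1:2]), c(0, 2))
  expect_equal(exp(out$Y), ds$Y)
  expect_identical(out$scale, "log")
  expect_error(log_transform(out), "already")

  ds0 <- toy_dataset(matrix(c(0, 1, 2), 1), edges, cov, 2,
                     scale = "natural")
  expect_error(log_transform(ds0), "offset")
  expect_equal(unname(log_transform(ds0, offset = 1)$Y[1, 1]), 0)
})

test_that("a single batch yields null batch effects and an identity map", {
  p <- make_parcellation(10, "uniform")
  spec <- cohort_spec(n_group_a = 15, n_group_b = 15, n_nodes = 10,
                      edge_density = 0.5, batch_shift = 0, batch_scale = 1,
                      seed = 51)
  ds <- log_transform(filter_edges(simulate_cohort(spec, p)))
  model <- fit_combat(ds)
  expect_lt(max(abs(model$gamma_star)), 1e-6)
  expect_lt(max(abs(model$delta_star^2 - 1)), 1e-6)
  harmonized <- apply_combat(model, ds)
  expect_lt(max(abs(harmonized$Y - ds$Y)), 1e-8)
})

test_that("iteration limit zero returns the naive batch estimates", {
  ds <- make_two_batch_dataset(seed = 61, n_per_group = 30)
  model <- fit_combat(ds, max_iter = 0L)
  expect_identical(model$gamma_star, model$gamma_hat)
  expect_identical(model$delta_star, sqrt(model$delta2_hat))
})

test_that("two-batch harmonization removes location/scale batch effects", {
  ds <- make_two_batch_dataset(seed = 71)
  b <- ds$covariates$batch
  model <- fit_combat(ds)
  harmonized <- apply_combat(model, ds)

  batch_diff <- function(Y) rowMeans(Y[, b == "batch2"]) -
    rowMeans(Y[, b == "batch1"])
  pre <- batch_diff(ds$Y)
  post <- batch_diff(harmonized$Y)
  expect_gt(1 - mean(abs(post)) / mean(abs(pre)), 0.9)

  var_ratio <- apply(harmonized$Y[, b == "batch2"], 1, var) /
    apply(harmonized$Y[, b == "batch1"], 1, var)
  expect_gt(median(var_ratio), 0.8)
  expect_lt(median(var_ratio), 1.25)

  # posterior shift estimate recovers the planted generative shift
  gdiff <- (model$gamma_star[2, ] - model$gamma_star[1, ]) *
    sqrt(model$pooled_var)
  se <- sd(gdiff) / sqrt(length(gdiff))
  expect_lt(abs(mean(gdiff) - 1), 3 * se)
})

test_that("group effects are preserved through harmonization", {
  ds <- make_two_batch_dataset(seed = 81)
  g <- ds$covariates$group
  model <- fit_combat(ds)
  harmonized <- apply_combat(model, ds)
  gd <- function(Y) rowMeans(Y[, g == "TLE"]) - rowMeans(Y[, g == "HC"])
  expect_gt(cor(gd(ds$Y), gd(harmonized$Y)), 0.95)
})

test_that("harmonization is idempotent in expectation", {
  ds <- make_two_batch_dataset(seed = 91)
  harmonized <- apply_combat(fit_combat(ds), ds)
  refit <- fit_combat(harmonized)
  expect_lt(max(abs(refit$gamma_star)), 0.05)
  expect_lt(max(abs(refit$delta_star^2 - 1)), 0.15)
})

test_that("harmonized output agrees with the reference ComBat implementation", {
  skip_if_not_installed("sva")
  ds <- make_two_batch_dataset(seed = 111)
  mine <- apply_combat(fit_combat(ds), ds)
  mod <- stats::model.matrix(~ group + age + sex, ds$covariates)
  ref <- suppressMessages(
    sva::ComBat(dat = ds$Y, batch = ds$covariates$batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE))
  expect_gt(cor(as.numeric(mine$Y), as.numeric(ref)), 0.9999)
  expect_lt(mean(abs(mine$Y - ref)), 0.02)
})

test_that("degenerate batch structures are rejected", {
  ds <- make_two_batch_dataset(seed = 121, n_per_group = 10)
  ds$covariates$batch <- factor(c("b1",
                                  rep("b2", nrow(ds$covariates) - 1L)))
  expect_error(fit_combat(ds), "at least 2 subjects")

  ds2 <- make_two_batch_dataset(seed = 121, n_per_group = 10)
  model <- fit_combat(ds2)
  ds_new <- ds2
  levels_new <- c(levels(ds2$covariates$batch), "batch9")
  ds_new$covariates$batch <- factor(rep("batch9", nrow(ds2$covariates)),
                                    levels = levels_new)
  expect_error(apply_combat(model, ds_new), "unseen")
})
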