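#' Specify a synthetic connectome cohort
#'
#' Collects the generative parameters for [simulate_cohort()]. Defaults
#' emulate a two-group epilepsy connectome study: 50 controls ("HC") and 92
#' patients ("TLE"), 162 nodes, two scanner-software batches with an additive
#' shift on log edge weights and a multiplicative effect on their noise,
#' ages uniform on 18-60 years, and a connected subnetwork of edges on which
#' the patient group's mean log weight is decreased.
#'
#' Edge weights follow a log-normal model: for present edge e and subject i,
#' \deqn{\log w_{ei} = \mu_e - s \,\sigma_e \,[i \in B][e \in planted]
#'   + \beta_{age} age_i + \beta_{sex} sex_i + shift_{b(i)}
#'   + scale_{b(i)} \,\epsilon_{ei},\quad \epsilon_{ei} \sim N(0, \sigma_e)}
#' with `s = effect_size` (a standardized decrease). Absent edges are zero
#' for every subject (shared support mask).
#'
#' @param n_group_a,n_group_b subjects in group A ("HC") and group B ("TLE").
#' @param n_nodes number of parcellation nodes.
#' @param edge_density fraction of node pairs that carry a connection.
#' @param effect_size standardized mean log-weight decrease planted on group B.
#' @param planted_edge_fraction fraction of present edges carrying the effect.
#' @param beta_age,beta_sex covariate slopes on the log-weight scale
#'   (per year; per sex = 1).
#' @param batch_shift,batch_scale per-batch additive shift and multiplicative
#'   noise scale (both length = number of batches; `batch_scale > 0`).
#' @param age_range ages are drawn uniformly over this range (years).
#' @param planted_connected require the planted edges to form a connected
#'   subgraph.
#' @param edge_log_mean,edge_log_sd mean/SD of the per-edge baseline
#'   log-weights \eqn{\mu_e}.
#' @param noise_sd_range range of the per-edge noise SD \eqn{\sigma_e}.
#' @param seed integer seed; identical specs reproduce identical cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 50L, n_group_b = 92L, n_nodes = 162L,
                        edge_density = 0.30, effect_size = 0.8,
                        planted_edge_fraction = 0.02,
                        beta_age = -0.01, beta_sex = 0.1,
                        batch_shift = c(0, 0.5), batch_scale = c(1, 1.2),
                        age_range = c(18, 60), planted_connected = TRUE,
                        edge_log_mean = 1, edge_log_sd = 0.5,
                        noise_sd_range = c(0.3, 0.6), seed = 1L) {
  if (n_group_a < 1 || n_group_b < 1) stop("group counts must be positive")
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (edge_density <= 0 || edge_density > 1)
    stop("edge_density must be in (0, 1]")
  if (planted_edge_fraction < 0 || planted_edge_fraction > 1)
    stop("planted_edge_fraction must be in [0, 1]")
  if (length(batch_shift) != length(batch_scale))
    stop("batch_shift and batch_scale must have the same length")
  if (any(batch_scale <= 0)) stop("batch_scale must be > 0")
  if (diff(range(age_range)) < 0) stop("age_range must be increasing")
  spec <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_nodes = as.integer(n_nodes), edge_density = edge_density,
    effect_size = effect_size,
    planted_edge_fraction = planted_edge_fraction,
    beta_age = beta_age, beta_sex = beta_sex,
    batch_shift = batch_shift, batch_scale = batch_scale,
    age_range = age_range, planted_connected = isTRUE(planted_connected),
    edge_log_mean = edge_log_mean, edge_log_sd = edge_log_sd,
    noise_sd_range = noise_sd_range, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

# grow a connected edge set of the requested size inside the support graph
grow_planted_edges <- function(support_edges, n_planted) {
  if (n_planted == 0L) return(integer(0))
  n_edges <- nrow(support_edges)
  if (n_planted > n_edges)
    stop("planted_edge_fraction exceeds the available edge support")
  start <- sample.int(n_edges, 1L)
  chosen <- start
  nodes <- c(support_edges[start, 1L], support_edges[start, 2L])
  while (length(chosen) < n_planted) {
    frontier <- setdiff(
      which(support_edges[, 1L] %in% nodes | support_edges[, 2L] %in% nodes),
      chosen)
    if (length(frontier) == 0L)
      stop("cannot grow a connected planted subgraph of ", n_planted,
           " edges; increase edge_density or lower planted_edge_fraction")
    nxt <- frontier[sample.int(length(frontier), 1L)]
    chosen <- c(chosen, nxt)
    nodes <- union(nodes, c(support_edges[nxt, 1L], support_edges[nxt, 2L]))
  }
  sort(chosen)
}

#' Simulate a synthetic connectome cohort
#'
#' Draws per-subject symmetric nonnegative connectivity matrices under the
#' log-normal edge-weight model described in [cohort_spec()], together with a
#' covariate table (group, age, sex, batch and subgroup labels) and the
#' ground-truth set of planted edges.
#'
#' Group B subjects additionally carry subgroup labels emulating clinical
#' strata: a seizure-history label (`fbtc`: "FBTC+"/"FBTC-") and a cognitive
#' impairment cluster (`impairment`: none/focal/generalized); group A
#' subjects carry `"HC"` in both columns so subgroup contrasts against
#' controls can reuse the same machinery. Neither label carries a planted
#' effect.
#'
#' @param spec a [cohort_spec()].
#' @param parcellation a [make_parcellation()] result with
#'   `spec$n_nodes` nodes.
#' @return A list of class `synthetic_cohort` with elements `matrices`
#'   (list of n x n matrices on the natural weight scale), `covariates`
#'   (data.frame: subject_id, group, age, sex, batch, fbtc, impairment),
#'   `truth` (data.frame: node_i, node_j, effect — 0-based node ids, signed
#'   log-scale effect), `support` (logical n x n shared support mask),
#'   `parcellation`, and `spec`.
#' @examples
#' p <- make_parcellation(20, "uniform")
#' spec <- cohort_spec(n_group_a = 10, n_group_b = 10, n_nodes = 20,
#'                     batch_shift = 0, batch_scale = 1, seed = 7)
#' cohort <- simulate_cohort(spec, p)
#' @export
simulate_cohort <- function(spec, parcellation) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  stop_if_not_parcellation(parcellation)
  if (nrow(parcellation) != spec$n_nodes)
    stop("parcellation node count does not match spec$n_nodes")
  set.seed(spec$seed)

  n <- spec$n_group_a + spec$n_group_b
  n_nodes <- spec$n_nodes
  group <- factor(rep(c("HC", "TLE"), c(spec$n_group_a, spec$n_group_b)),
                  levels = c("HC", "TLE"))
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  sex <- rbinom(n, 1L, 0.5)
  n_batches <- length(spec$batch_shift)
  batch <- factor(sample(rep_len(paste0("batch", seq_len(n_batches)), n)),
                  levels = paste0("batch", seq_len(n_batches)))

  # subgroup labels for group B, proportions mirroring the emulated study
  is_b <- group == "TLE"
  fbtc <- rep("HC", n)
  fbtc[is_b] <- sample(c("FBTC+", "FBTC-"), sum(is_b), replace = TRUE,
                       prob = c(62, 21) / 83)
  impairment <- rep("HC", n)
  impairment[is_b] <- sample(c("none", "focal", "generalized"), sum(is_b),
                             replace = TRUE, prob = c(41, 25, 9) / 75)

  # shared edge support over the upper triangle, lexicographic (i, j)
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  n_pairs <- nrow(pairs)
  n_present <- max(1L, round(spec$edge_density * n_pairs))
  present <- sort(sample.int(n_pairs, n_present))
  edges <- pairs[present, , drop = FALSE] # 1-based rows/cols

  n_planted <- round(spec$planted_edge_fraction * n_present)
  planted_idx <- if (spec$planted_connected) {
    grow_planted_edges(edges, n_planted)
  } else if (n_planted > 0L) {
    sort(sample.int(n_present, n_planted))
  } else integer(0)

  mu_e <- rnorm(n_present, spec$edge_log_mean, spec$edge_log_sd)
  sigma_e <- runif(n_present, spec$noise_sd_range[1], spec$noise_sd_range[2])

  effect <- numeric(n_present)
  effect[planted_idx] <- -spec$effect_size * sigma_e[planted_idx]

  b_idx <- as.integer(batch)
  eps <- matrix(rnorm(n_present * n), n_present, n) * sigma_e
  logw <- mu_e +
    outer(effect, as.numeric(is_b)) +
    outer(rep(1, n_present), spec$beta_age * age + spec$beta_sex * sex +
            spec$batch_shift[b_idx]) +
    eps * rep(spec$batch_scale[b_idx], each = n_present)
  w <- exp(logw)

  matrices <- lapply(seq_len(n), function(i) {
    m <- matrix(0, n_nodes, n_nodes)
    m[edges] <- w[, i]
    m[edges[, c(2L, 1L), drop = FALSE]] <- w[, i]
    m
  })

  support <- matrix(FALSE, n_nodes, n_nodes)
  support[edges] <- TRUE
  support[edges[, c(2L, 1L), drop = FALSE]] <- TRUE

  covariates <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, age = age, sex = sex, batch = batch,
    fbtc = fbtc, impairment = impairment,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    node_i = edges[planted_idx, 1L] - 1L,
    node_j = edges[planted_idx, 2L] - 1L,
    effect = effect[planted_idx]
  )

  out <- list(matrices = matrices, covariates = covariates, truth = truth,
              support = support, parcellation = parcellation, spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$matrices), "subjects,",
      nrow(x$parcellation), "nodes,",
      sum(x$support[upper.tri(x$support)]), "edges,",
      nrow(x$truth), "planted\n")
  print(table(group = x$covariates$group, batch = x$covariates$batch))
  invisible(x)
}

#' Ground-truth mask of planted edges
#'
#' @param cohort a [simulate_cohort()] result.
#' @return Symmetric logical matrix, `TRUE` on planted edges, zero diagonal.
#' @export
truth_mask <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop("cohort must come from simulate_cohort()")
  n <- nrow(cohort$parcellation)
  m <- matrix(FALSE, n, n)
  if (nrow(cohort$truth)) {
    ij <- cbind(cohort$truth$node_i + 1L, cohort$truth$node_j + 1L)
    m[ij] <- TRUE
    m[ij[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  m
}
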