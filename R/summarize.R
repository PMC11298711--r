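#' Significant-edge mask at a given alpha
#'
#' @param pgraphs a [permutation_pvalues()] result.
#' @param alpha significance level in (0, 1); edges with `p <= alpha` are
#'   flagged.
#' @param correction `"corrected"` (max-null, family-wise error) or
#'   `"uncorrected"` (connection-specific null).
#' @return A list with `mask` (symmetric logical matrix) and `count`
#'   (number of significant upper-triangle edges).
#' @export
significant_edges <- function(pgraphs, alpha = 0.05,
                              correction = c("corrected", "uncorrected")) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  pm <- if (correction == "corrected") pgraphs$p_corrected else
    pgraphs$p_uncorrected
  edges <- pgraphs$edges
  ij <- cbind(edges$node_i + 1L, edges$node_j + 1L)
  sig <- pm[ij] <= alpha
  mask <- matrix(FALSE, nrow(pm), ncol(pm))
  mask[ij] <- sig
  mask[ij[, c(2L, 1L), drop = FALSE]] <- sig
  list(mask = mask, count = sum(sig), alpha = alpha, correction = correction)
}

#' Lobe-pair summary of significant connections
#'
#' Assigns each significant edge to the unordered pair of lobe classes of
#' its endpoints (15 pairs over the five classes) and reports counts and
#' percentages. By default percentages are relative to the total number of
#' significant edges in the stratum ("percentage of significant
#' connections"); `denominator = "possible"` instead normalizes by the
#' number of network edges available in each lobe pair.
#'
#' @param mask symmetric logical significance mask (or the list returned by
#'   [significant_edges()]).
#' @param parcellation a [make_parcellation()] result covering all nodes.
#' @param direction label recorded in the table (`"decrease"` or
#'   `"increase"`).
#' @param correction label recorded in the table.
#' @param denominator `"significant"` or `"possible"`.
#' @param support optional symmetric logical matrix of network edges
#'   (required for `denominator = "possible"`).
#' @return A data.frame of class `lobe_pair_summary` with one row per
#'   unordered lobe pair: `lobe_a`, `lobe_b`, `n_significant`,
#'   `percent_of_significant`, `direction`, `correction`.
#' @export
lobe_pair_summary <- function(mask, parcellation,
                              direction = c("decrease", "increase"),
                              correction = c("corrected", "uncorrected"),
                              denominator = c("significant", "possible"),
                              support = NULL) {
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  denominator <- match.arg(denominator)
  if (is.list(mask) && !is.matrix(mask)) mask <- mask$mask
  stop_if_not_parcellation(parcellation)
  if (nrow(mask) != nrow(parcellation))
    stop("mask dimension does not match parcellation node count")
  if (!isTRUE(all.equal(mask, t(mask)))) stop("mask must be symmetric")

  lobes <- c("frontal", "occipital", "parietal", "temporal", "subcortical")
  node_lobe <- parcellation$lobe[order(parcellation$node_id)]
  if (!all(node_lobe %in% lobes))
    stop("parcellation contains unknown lobe classes")

  pairs <- expand.grid(a = seq_along(lobes), b = seq_along(lobes))
  pairs <- pairs[pairs$a <= pairs$b, ]
  key <- function(la, lb) paste(pmin(la, lb), pmax(la, lb), sep = "|")
  tab <- setNames(numeric(nrow(pairs)), key(lobes[pairs$a], lobes[pairs$b]))

  idx <- which(mask & upper.tri(mask), arr.ind = TRUE)
  if (nrow(idx)) {
    k <- key(node_lobe[idx[, 1L]], node_lobe[idx[, 2L]])
    counts <- table(k)
    tab[names(counts)] <- as.numeric(counts)
  }

  if (denominator == "significant") {
    total <- sum(tab)
    pct <- if (total > 0) 100 * tab / total else tab * 0
  } else {
    if (is.null(support))
      stop("denominator = 'possible' requires the network support mask")
    sup_idx <- which(support & upper.tri(support), arr.ind = TRUE)
    possible <- setNames(numeric(nrow(pairs)), names(tab))
    if (nrow(sup_idx)) {
      ks <- key(node_lobe[sup_idx[, 1L]], node_lobe[sup_idx[, 2L]])
      cs <- table(ks)
      possible[names(cs)] <- as.numeric(cs)
    }
    pct <- ifelse(possible > 0, 100 * tab / possible, 0)
  }

  out <- data.frame(
    lobe_a = lobes[pairs$a], lobe_b = lobes[pairs$b],
    n_significant = as.numeric(tab),
    percent_of_significant = as.numeric(pct),
    direction = direction, correction = correction,
    stringsAsFactors = FALSE
  )
  class(out) <- c("lobe_pair_summary", "data.frame")
  out
}

#' Top connections ranked by corrected p-value
#'
#' Returns the significant edges (corrected `p <= alpha`) sorted ascending
#' by corrected p-value, ties broken by `|t|` descending and then by
#' lexicographic edge id, with region names attached.
#'
#' @param pgraphs a [permutation_pvalues()] result.
#' @param parcellation the node parcellation.
#' @param k maximum number of connections to return (>= 1).
#' @param alpha significance cutoff applied before ranking.
#' @return A data.frame with columns `node_i`, `node_j`, `region_i`,
#'   `region_j`, `lobe_i`, `lobe_j`, `t`, `p_corrected`, `p_uncorrected`.
#' @export
top_connections <- function(pgraphs, parcellation, k = 16L, alpha = 0.05) {
  if (k < 1) stop("k must be >= 1")
  stop_if_not_parcellation(parcellation)
  edges <- pgraphs$edges
  ij <- cbind(edges$node_i + 1L, edges$node_j + 1L)
  df <- data.frame(
    node_i = edges$node_i, node_j = edges$node_j,
    t = pgraphs$t[ij],
    p_corrected = pgraphs$p_corrected[ij],
    p_uncorrected = pgraphs$p_uncorrected[ij]
  )
  df <- df[df$p_corrected <= alpha, , drop = FALSE]
  if (nrow(df) < k)
    message("top_connections: only ", nrow(df),
            " significant connection(s) at alpha = ", alpha,
            "; returning all of them")
  ord <- order(df$p_corrected, -abs(df$t), df$node_i, df$node_j)
  df <- head(df[ord, , drop = FALSE], k)
  look <- parcellation[order(parcellation$node_id), ]
  df$region_i <- look$region_name[df$node_i + 1L]
  df$region_j <- look$region_name[df$node_j + 1L]
  df$lobe_i <- look$lobe[df$node_i + 1L]
  df$lobe_j <- look$lobe[df$node_j + 1L]
  rownames(df) <- NULL
  df[, c("node_i", "node_j", "region_i", "region_j", "lobe_i", "lobe_j",
         "t", "p_corrected", "p_uncorrected")]
}

#' Tidy nuisance-adjusted values for selected edges
#'
#' Extracts per-subject nuisance-adjusted edge values (see
#' [residualize_adjusted()]) for a set of edges, in the long format used
#' for group box plots of representative connections.
#'
#' @param dataset a `cohort_dataset`.
#' @param edges data.frame with `node_i`, `node_j` (0-based) naming edges
#'   present in the dataset.
#' @param design a [build_design()] result.
#' @return A data.frame: `subject_id`, `group`, `node_i`, `node_j`, `edge`,
#'   `adjusted`.
#' @export
extract_adjusted <- function(dataset, edges, design) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  key_all <- paste0(dataset$edges$node_i, "-", dataset$edges$node_j)
  key_req <- paste0(edges$node_i, "-", edges$node_j)
  pos <- match(key_req, key_all)
  if (anyNA(pos))
    stop("unknown edge(s): ", paste(key_req[is.na(pos)], collapse = ", "))
  adj <- residualize_adjusted(dataset, design)
  cov <- dataset$covariates[design$keep, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_along(pos), function(r) {
    data.frame(
      subject_id = cov$subject_id,
      group = as.character(cov[[design$group_column]]),
      node_i = edges$node_i[r], node_j = edges$node_j[r],
      edge = key_req[r],
      adjusted = adj[pos[r], ],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
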