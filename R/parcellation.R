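#' Build a node parcellation lookup
#'
#' Maps node indices of a connectivity matrix to region names, lobe classes
#' and hemispheres. Two schemes are available:
#' \describe{
#'   \item{`destrieux162`}{A 162-node layout with 81 nodes per hemisphere
#'     (74 cortical + 7 subcortical), the geometry of the IIT/Destrieux-style
#'     cortico-subcortical parcellations used for structural connectomes.
#'     Region names and per-lobe counts are a synthetic stand-in with
#'     representative proportions, not the actual atlas lookup table.}
#'   \item{`uniform`}{Round-robin assignment of nodes over the five lobe
#'     classes, alternating hemisphere on each full cycle; useful for small
#'     toy networks.}
#' }
#'
#' @param n_nodes integer, number of nodes (>= 2). Must be 162 for
#'   `destrieux162`.
#' @param scheme `"destrieux162"` or `"uniform"`.
#' @return A data.frame of class `parcellation` with columns `node_id`
#'   (0-based contiguous integers), `region_name`, `lobe` (one of frontal,
#'   occipital, parietal, temporal, subcortical) and `hemisphere`
#'   (left/right).
#' @examples
#' p <- make_parcellation(10, "uniform")
#' table(p$lobe)
#' @export
make_parcellation <- function(n_nodes, scheme = c("destrieux162", "uniform")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2)
    stop("n_nodes must be a single integer >= 2")
  n_nodes <- as.integer(n_nodes)
  lobes <- c("frontal", "occipital", "parietal", "temporal", "subcortical")

  if (scheme == "destrieux162") {
    if (n_nodes != 162L)
      stop("scheme 'destrieux162' requires n_nodes = 162")
    # representative per-hemisphere counts: 74 cortical + 7 subcortical
    counts <- c(frontal = 26L, parietal = 16L, temporal = 18L,
                occipital = 14L, subcortical = 7L)
    one_hemi <- function(h) {
      lobe <- rep(names(counts), counts)
      data.frame(
        region_name = paste0(substr(h, 1, 1), "h_", lobe, "_",
                             unlist(lapply(counts, seq_len))),
        lobe = lobe,
        hemisphere = h,
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(one_hemi("left"), one_hemi("right"))
  } else {
    lobe <- lobes[(seq_len(n_nodes) - 1L) %% 5L + 1L]
    hemisphere <- ifelse(((seq_len(n_nodes) - 1L) %/% 5L) %% 2L == 0L,
                         "left", "right")
    out <- data.frame(
      region_name = paste0(substr(hemisphere, 1, 1), "h_", lobe, "_",
                           stats::ave(seq_len(n_nodes),
                                      paste(lobe, hemisphere),
                                      FUN = seq_along)),
      lobe = lobe,
      hemisphere = hemisphere,
      stringsAsFactors = FALSE
    )
  }
  out <- cbind(node_id = seq_len(nrow(out)) - 1L, out)
  rownames(out) <- NULL
  class(out) <- c("parcellation", "data.frame")
  out
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", nrow(x), "nodes\n")
  print(table(lobe = x$lobe, hemisphere = x$hemisphere))
  invisible(x)
}

stop_if_not_parcellation <- function(p) {
  if (!inherits(p, "parcellation"))
    stop("expected a 'parcellation' object (see make_parcellation())")
  needed <- c("node_id", "region_name", "lobe", "hemisphere")
  if (!all(needed %in% names(p)))
    stop("parcellation is missing columns: ",
         paste(setdiff(needed, names(p)), collapse = ", "))
  if (anyNA(p$lobe)) stop("parcellation has nodes with missing lobe")
  invisible(p)
}
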