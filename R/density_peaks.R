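# Density-peak calling: the pipeline's core computation.
#
# The density signal counts ZFBS-morph-overlap hit starts inside an 850-base
# sliding window. Two hit starts co-occur in at least one window position
# iff they differ by at most window_w - 1; single-linkage closure of that
# relation partitions hits into clusters, and clusters below min_hits
# (isolated overlaps) are discarded as background noise. Each surviving
# cluster is one peak.

#' Density-peak calling parameters
#'
#' @param window_w Sliding-window width in bases. Default 850, chosen in the
#'   original analysis by trial and error: larger windows tend to merge
#'   unrelated hits into false peaks, smaller windows fragment true clusters
#'   into spiky singletons.
#' @param min_hits Minimum cluster size for a peak. Default 2; size-1
#'   clusters are the "isolated overlaps" suppressed as noise.
#' @param tier_thresholds Named integer vector mapping tier labels to the
#'   minimum `n_hits` for that tier; must be strictly increasing. A peak
#'   covering 2 overlaps may be a false positive ("candidate"), 3 is more
#'   reliable ("robust"), and >= 4 is labelled "very_robust" by default (the
#'   boundary above "robust" is configurable; reported very robust peaks
#'   such as the 7-overlap cattle KvDMR1 peak sit well above it).
#' @return An object of class `density_params`.
#' @export
density_params <- function(window_w = 850L, min_hits = 2L,
                           tier_thresholds = c(candidate = 2L, robust = 3L,
                                               very_robust = 4L)) {
  window_w <- as.integer(window_w)
  min_hits <- as.integer(min_hits)
  if (is.na(window_w) || window_w < 2L) stop("'window_w' must be >= 2")
  if (is.na(min_hits) || min_hits < 2L) stop("'min_hits' must be >= 2")
  if (is.null(names(tier_thresholds)) || any(!nzchar(names(tier_thresholds))))
    stop("'tier_thresholds' must be a named vector")
  tt <- as.integer(tier_thresholds)
  names(tt) <- names(tier_thresholds)
  if (any(diff(tt) <= 0L)) stop("'tier_thresholds' must be strictly increasing")
  structure(list(window_w = window_w, min_hits = min_hits,
                 tier_thresholds = tt),
            class = "density_params")
}

#' @export
print.density_params <- function(x, ...) {
  cat(sprintf("<density_params> window %d bp, min %d hits; tiers: %s\n",
              x$window_w, x$min_hits,
              paste(sprintf("%s>=%d", names(x$tier_thresholds),
                            x$tier_thresholds), collapse = ", ")))
  invisible(x)
}

#' Count hit starts inside one window
#'
#' Number of hit start positions `s` with `p <= s < p + window_w`.
#'
#' @param starts Sorted ascending hit start positions.
#' @param p Window anchor position (0-based).
#' @param params A [density_params()].
#' @return Integer count.
#' @export
#' @examples
#' window_count(c(100, 500), 100, density_params())  # 2
#' window_count(c(100, 950), 100, density_params())  # 1: 950 excluded
window_count <- function(starts, p, params = density_params()) {
  if (is.unsorted(starts)) stop("'starts' must be sorted ascending")
  sum(starts >= p & starts < p + params$window_w)
}

#' Assign confidence tiers to peak hit counts
#'
#' The tier is the highest label whose threshold does not exceed `n_hits`.
#' With the defaults: 2 hits -> `candidate` (could be a false positive),
#' 3 -> `robust` (more reliable), >= 4 -> `very_robust`.
#'
#' @param n_hits Integer vector of cluster sizes (each >= 2).
#' @param tier_thresholds As in [density_params()].
#' @return Character vector of tier labels.
#' @export
#' @examples
#' assign_tier(c(2, 3, 7))
assign_tier <- function(n_hits,
                        tier_thresholds = density_params()$tier_thresholds) {
  n_hits <- as.integer(n_hits)
  if (any(is.na(n_hits)) || any(n_hits < 2L))
    stop("'n_hits' must be >= 2 (size-1 clusters are suppressed, not tiered)")
  tt <- as.integer(tier_thresholds)
  if (any(n_hits < tt[1]))
    stop("'n_hits' below the lowest tier threshold")
  names(tier_thresholds)[findInterval(n_hits, tt)]
}

#' Cluster composite-motif hits into density peaks
#'
#' Single-linkage clustering of hit start positions under the co-window
#' rule: consecutive starts are linked iff they differ by at most
#' `window_w - 1` bases (i.e. both fall inside at least one common
#' sliding-window position). Clusters smaller than `min_hits` — isolated
#' overlaps — are discarded. Each surviving cluster becomes one peak whose
#' footprint is `[min member start, max member end)`.
#'
#' Two peak scores are reported: `n_hits`, the cluster size (used for
#' tiers), and `max_window_count`, the largest number of member starts that
#' fit in any single window — these differ when a cluster chains across
#' more than one window width.
#'
#' @param hits Hit data.frame for ONE chromosome, all of class
#'   `ZFBS_MORPH`, sorted by start (as produced by [scan_chromosome()]).
#' @param params A [density_params()].
#' @return A data.frame of class `density_peaks` with columns `chrom`,
#'   `start`, `end`, `n_hits`, `max_window_count`, `tier`, plus a
#'   list-column `members` holding each peak's member hits; sorted by
#'   start, non-overlapping.
#' @export
cluster_hits <- function(hits, params = density_params()) {
  stopifnot(is.data.frame(hits), inherits(params, "density_params"))
  peaks0 <- data.frame(chrom = character(), start = integer(), end = integer(),
                       n_hits = integer(), max_window_count = integer(),
                       tier = character(), stringsAsFactors = FALSE)
  peaks0$members <- list()
  class(peaks0) <- c("density_peaks", "data.frame")
  attr(peaks0, "params") <- params
  if (nrow(hits) == 0L) return(peaks0)
  if (length(unique(hits$chrom)) > 1L)
    stop("cluster_hits() expects hits from a single chromosome")
  if (any(hits$motif_class != "ZFBS_MORPH"))
    stop("density is computed from ZFBS_MORPH hits only")
  if (is.unsorted(hits$start)) stop("hits must be sorted by start")

  s <- hits$start
  W <- params$window_w
  cl <- cumsum(c(1L, as.integer(diff(s) > W - 1L)))
  keep_cl <- which(tabulate(cl) >= params$min_hits)
  rows <- lapply(keep_cl, function(k) {
    idx <- which(cl == k)
    ss <- s[idx]
    # member starts within [ss[i], ss[i] + W) for each anchor i
    mwc <- max(vapply(seq_along(ss),
                      function(i) sum(ss >= ss[i] & ss < ss[i] + W),
                      integer(1)))
    list(chrom = hits$chrom[idx[1]], start = min(ss),
         end = max(hits$end[idx]), n_hits = length(idx),
         max_window_count = mwc,
         members = hits[idx, , drop = FALSE])
  })
  if (length(rows) == 0L) return(peaks0)
  peaks <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    n_hits = vapply(rows, `[[`, integer(1), "n_hits"),
    max_window_count = vapply(rows, `[[`, integer(1), "max_window_count"),
    stringsAsFactors = FALSE)
  peaks$tier <- assign_tier(peaks$n_hits, params$tier_thresholds)
  peaks$members <- lapply(rows, `[[`, "members")
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("density_peaks", "data.frame")
  attr(peaks, "params") <- params
  peaks
}

#' Collapse hits sharing a genomic footprint
#'
#' Optional pre-clustering deduplication (OFF by default in the pipeline):
#' among hits whose genomic intervals overlap, only the earliest-starting
#' one is retained (ties broken by longest interval, then lexicographic
#' `motif_id`). Use this to count a locus once when several composite
#' motifs, or both orientations of one motif, cover the same footprint.
#'
#' @param hits Sorted hit data.frame.
#' @return The surviving hits, same columns, sorted.
#' @export
collapse_cofootprint_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$chrom)) > 1L)
    stop("collapse_cofootprint_hits() expects hits from a single chromosome")
  if (is.unsorted(hits$start)) stop("hits must be sorted by start")
  # survivor-priority order inside an overlap component:
  # earliest start, then longest, then lexicographic motif_id
  ord <- order(hits$start, -(hits$end - hits$start), hits$motif_id)
  h <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(h))
  comp_end <- -1L
  for (i in seq_len(nrow(h))) {
    if (h$start[i] >= comp_end) {   # starts a new overlap component
      keep[i] <- TRUE
      comp_end <- h$end[i]
    } else {
      comp_end <- max(comp_end, h$end[i])
    }
  }
  sort_hits(h[keep, , drop = FALSE])
}

#' @export
print.density_peaks <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<density_peaks> %d peak(s)", nrow(x)))
  if (!is.null(p)) cat(sprintf(" (window %d bp, min %d hits)", p$window_w, p$min_hits))
  cat("\n")
  if (nrow(x)) {
    tab <- table(factor(x$tier, levels = names(p$tier_thresholds %||%
                                                 sort(unique(x$tier)))))
    cat("  tiers:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    print.data.frame(utils::head(x[, setdiff(names(x), "members")], 10))
    if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more\n")
  }
  invisible(x)
}
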