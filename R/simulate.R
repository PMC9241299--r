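# Seeded synthetic genomes with planted motif clusters and exact ground
# truth. The generator emulates the geometry the density method exploits:
# compact clusters of composite motifs (ICR-like) separated by long
# motif-free background, plus isolated single motifs that the peak caller
# must suppress. Background composition is i.i.d. with a configurable GC
# fraction; accidental background motif occurrences are resampled away so
# the planted truth is exact rather than probabilistic.

#' Configuration for a synthetic genome
#'
#' Defaults describe the standard test condition: a 100 kb chromosome at
#' GC 0.5 carrying 5 clusters of 2-7 motifs within 600-base spans and 10
#' isolated motifs, all features separated by at least 2,000 bases. With
#' `cluster_span <= window_w - max motif length` every planted cluster is
#' guaranteed to co-window, and with `min_separation > window_w` no two
#' features can ever link — so pipeline recovery of the truth is exact by
#' construction.
#'
#' @param genome_length Chromosome length in bases.
#' @param gc_fraction Background GC fraction in (0,1).
#' @param n_clusters Number of planted clusters.
#' @param cluster_size_range Integer pair: min/max motifs per cluster (min >= 2).
#' @param cluster_span Maximal width in bases a cluster's motifs occupy.
#' @param n_isolated Number of isolated planted motifs.
#' @param min_separation Minimal gap in bases between planted features;
#'   must exceed `window_w`.
#' @param seed Integer seed; the same seed reproduces the genome and truth
#'   byte for byte.
#' @param chrom Chromosome id of the synthetic record.
#' @param window_w Window width the genome is designed for (default 850).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, gc_fraction = 0.5,
                       n_clusters = 5L, cluster_size_range = c(2L, 7L),
                       cluster_span = 600L, n_isolated = 10L,
                       min_separation = 2000L, seed = 1L,
                       chrom = "chrS", window_w = 850L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction,
              n_clusters = as.integer(n_clusters),
              cluster_size_range = as.integer(cluster_size_range),
              cluster_span = as.integer(cluster_span),
              n_isolated = as.integer(n_isolated),
              min_separation = as.integer(min_separation),
              seed = as.integer(seed), chrom = chrom,
              window_w = as.integer(window_w))
  if (cfg$gc_fraction <= 0 || cfg$gc_fraction >= 1)
    stop("'gc_fraction' must be in (0,1)")
  if (length(cfg$cluster_size_range) != 2L || cfg$cluster_size_range[1] < 2L ||
      diff(cfg$cluster_size_range) < 0L)
    stop("'cluster_size_range' must be an increasing pair with min >= 2")
  if (cfg$min_separation <= cfg$window_w)
    stop("'min_separation' must exceed 'window_w' so isolated plants never link")
  structure(cfg, class = "sim_config")
}

# Replace accidental catalog-motif occurrences (both strands) in a
# background sequence by freshly drawn bases, repeating until clean.
scrub_background <- function(seq_chars, catalog, bases, probs,
                             max_attempts = 1000L) {
  g <- genome_sequence("bg", paste(seq_chars, collapse = ""))
  for (attempt in seq_len(max_attempts)) {
    hits <- scan_chromosome(g, catalog, strands = "both")
    if (nrow(hits) == 0L) return(strsplit(g$seq, "", fixed = TRUE)[[1]])
    chars <- strsplit(g$seq, "", fixed = TRUE)[[1]]
    idx <- unique(unlist(mapply(function(s, e) (s + 1L):e, hits$start,
                                hits$end, SIMPLIFY = FALSE)))
    chars[idx] <- sample(bases, length(idx), replace = TRUE, prob = probs)
    g <- genome_sequence("bg", paste(chars, collapse = ""))
  }
  stop(sprintf(paste("background still contains catalog motifs after %d",
                     "resampling rounds; the catalog is too dense for this",
                     "GC fraction/length — shorten motifs or change gc_fraction"),
               max_attempts))
}

# Draw non-overlapping motif placements inside one cluster span.
# Returns a data.frame(offset, len, motif_row, orient) sorted by offset.
draw_cluster_layout <- function(n_planted, span, motif_lens, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    rows <- sample.int(length(motif_lens), n_planted, replace = TRUE)
    lens <- motif_lens[rows]
    offs <- vapply(lens, function(l) sample.int(span - l + 1L, 1L) - 1L, integer(1))
    o <- order(offs)
    offs <- offs[o]; lens <- lens[o]; rows <- rows[o]
    if (all(diff(offs) >= lens[-length(lens)]))  # non-overlapping
      return(data.frame(offset = offs, len = lens, motif_row = rows,
                        orient = sample(c("fwd", "rev"), n_planted, replace = TRUE)))
  }
  stop("could not place non-overlapping motifs inside 'cluster_span'; widen it")
}

#' Simulate a genome with planted motif clusters and isolated motifs
#'
#' Draws an i.i.d. background with `P(G)=P(C)=gc/2`, `P(A)=P(T)=(1-gc)/2`,
#' resamples away any accidental occurrence of a catalog motif (either
#' strand), then plants `n_clusters` compact clusters and `n_isolated`
#' single motifs left-to-right with at least `min_separation` bases between
#' features. Planted motifs are drawn uniformly from the catalog and from
#' forward/reverse-complement orientation. After planting, the sequence is
#' re-scanned and planting is redrawn in the rare case a junction creates
#' an unplanned occurrence, so the returned truth is exact.
#'
#' With `scrub = FALSE` ("natural background" stress mode) accidental
#' background occurrences are left in place and the truth table describes
#' only the planted features.
#'
#' @param config A [sim_config()].
#' @param catalog The [motif_catalog()] whose motifs are planted (normally
#'   a `ZFBS_MORPH` catalog).
#' @param scrub Resample accidental background occurrences (default TRUE).
#' @return List with `genome` (a [genome_sequence()]) and `truth`, a
#'   data.frame `(chrom, start, end, kind, n_planted)` with one row per
#'   planted feature (`kind` is `"cluster"` or `"isolated"`), 0-based
#'   half-open, sorted by start.
#' @export
simulate_genome <- function(config, catalog, scrub = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "motif_catalog"))
  motif_lens <- nchar(catalog$motifs$sequence)
  if (config$cluster_span > config$window_w - max(motif_lens))
    stop("'cluster_span' must be <= window_w - max motif length so planted clusters always co-window")
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
             config$gc_fraction / 2, (1 - config$gc_fraction) / 2)

  with_seed(config$seed, {
    n_feat <- config$n_clusters + config$n_isolated
    kinds <- sample(rep(c("cluster", "isolated"),
                        c(config$n_clusters, config$n_isolated)))
    widths <- ifelse(kinds == "cluster", config$cluster_span, max(motif_lens))
    need <- sum(widths) + (n_feat - 1L) * config$min_separation
    if (n_feat > 0L && need > config$genome_length)
      stop("planted features plus separations exceed 'genome_length'")

    chars <- sample(bases, config$genome_length, replace = TRUE, prob = probs)
    if (scrub) chars <- scrub_background(chars, catalog, bases, probs)

    for (attempt in seq_len(50L)) {
      seq_chars <- chars
      truth <- NULL
      if (n_feat > 0L) {
        # distribute the slack over the n_feat + 1 gaps around features
        slack <- config$genome_length - need
        cuts <- sort(sample.int(slack + 1L, n_feat, replace = TRUE) - 1L)
        gaps <- diff(c(0L, cuts, slack))  # n_feat + 1 values summing to slack
        pos <- 0L
        truth_rows <- vector("list", n_feat)
        for (i in seq_len(n_feat)) {
          pos <- pos + gaps[i] + (if (i > 1L) config$min_separation else 0L)
          if (kinds[i] == "cluster") {
            rng <- config$cluster_size_range
            n_planted <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
            lay <- draw_cluster_layout(n_planted, config$cluster_span, motif_lens)
            for (j in seq_len(nrow(lay))) {
              m <- catalog$motifs$sequence[lay$motif_row[j]]
              if (lay$orient[j] == "rev") m <- revcomp(m)
              at <- pos + lay$offset[j]
              seq_chars[(at + 1L):(at + lay$len[j])] <-
                strsplit(m, "", fixed = TRUE)[[1]]
            }
            truth_rows[[i]] <- data.frame(
              chrom = config$chrom, start = pos + min(lay$offset),
              end = pos + max(lay$offset + lay$len), kind = "cluster",
              n_planted = n_planted, stringsAsFactors = FALSE)
          } else {
            row <- sample.int(nrow(catalog$motifs), 1L)
            m <- catalog$motifs$sequence[row]
            if (sample(c(TRUE, FALSE), 1L)) m <- revcomp(m)
            len <- nchar(m)
            seq_chars[(pos + 1L):(pos + len)] <- strsplit(m, "", fixed = TRUE)[[1]]
            truth_rows[[i]] <- data.frame(
              chrom = config$chrom, start = pos, end = pos + len,
              kind = "isolated", n_planted = 1L, stringsAsFactors = FALSE)
          }
          pos <- pos + widths[i]
        }
        truth <- do.call(rbind, truth_rows)
      }
      if (is.null(truth))
        truth <- data.frame(chrom = character(), start = integer(),
                            end = integer(), kind = character(),
                            n_planted = integer(), stringsAsFactors = FALSE)
      genome <- genome_sequence(config$chrom, paste(seq_chars, collapse = ""))
      if (!scrub || planting_is_exact(genome, catalog, truth))
        return(list(genome = genome, truth = truth[order(truth$start), ,
                                                   drop = FALSE]))
      # junction artifact: redraw gap layout and cluster contents
    }
    stop("planting repeatedly produced unplanned motif occurrences; check the catalog for motifs nested in one another")
  })
}

# TRUE iff a scan finds exactly n_planted hits inside each truth feature
# and none outside.
planting_is_exact <- function(genome, catalog, truth) {
  hits <- scan_chromosome(genome, catalog, strands = "both")
  if (nrow(truth) == 0L) return(nrow(hits) == 0L)
  feat <- rep(NA_integer_, nrow(hits))
  for (i in seq_len(nrow(truth)))
    feat[hits$start >= truth$start[i] & hits$end <= truth$end[i]] <- i
  if (anyNA(feat)) return(FALSE)
  counts <- tabulate(feat, nbins = nrow(truth))
  all(counts == truth$n_planted)
}

#' Write / read a planted-truth table
#'
#' BED-like TSV with header: `chrom start end kind n_planted`, 0-based
#' half-open.
#'
#' @param truth The truth data.frame from [simulate_genome()].
#' @param path File path.
#' @return `path` (writer) or the truth data.frame (reader).
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  if (!file.exists(path)) input_error("truth file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Score called peaks against planted truth
#'
#' A truth cluster is recovered when at least one peak overlaps it by >= 1
#' bp. Precision is the fraction of peaks overlapping some truth cluster;
#' recall the fraction of truth clusters recovered; `count_exact` the
#' fraction of recovered clusters whose best-overlapping peak has `n_hits`
#' equal to the planted count. Isolated truth features are ignored here —
#' they are what the caller must suppress; check suppression separately by
#' asking whether any peak overlaps a `kind == "isolated"` truth row.
#'
#' @param peaks A [cluster_hits()] result.
#' @param truth A truth table from [simulate_genome()].
#' @return List with `precision`, `recall`, `count_exact` (each in `[0,1]`;
#'   `precision` is `NA` when there are no peaks, `count_exact` `NA` when
#'   nothing was recovered).
#' @export
evaluate_recovery <- function(peaks, truth) {
  clusters <- truth[truth$kind == "cluster", , drop = FALSE]
  if (nrow(clusters) == 0L)
    return(list(precision = if (nrow(peaks)) 0 else NA_real_,
                recall = NA_real_, count_exact = NA_real_))
  if (nrow(peaks) == 0L)
    return(list(precision = NA_real_, recall = 0, count_exact = NA_real_))
  pk <- IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  tr <- IRanges::IRanges(start = clusters$start + 1L, end = clusters$end)
  ov <- IRanges::findOverlaps(tr, pk, minoverlap = 1L)
  recovered <- unique(S4Vectors::queryHits(ov))
  matching_peaks <- unique(S4Vectors::subjectHits(ov))
  exact <- vapply(recovered, function(i) {
    js <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    widths <- IRanges::width(IRanges::pintersect(rep(tr[i], length(js)), pk[js]))
    best <- js[which.max(widths)]
    peaks$n_hits[best] == clusters$n_planted[i]
  }, logical(1))
  list(precision = length(matching_peaks) / nrow(peaks),
       recall = length(recovered) / nrow(clusters),
       count_exact = if (length(recovered)) mean(exact) else NA_real_)
}
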