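#' Run the full candidate-ICR scan
#'
#' The whole two-stage workflow in one call: exact-match scan of every
#' chromosome for the ZFP57 and ZFBS-morph-overlap catalogs, then
#' sliding-window density-peak calling on the composite-motif hits, with
#' isolated overlaps suppressed and peaks tiered by the number of overlaps
#' they cover. Plain ZFP57 hits are never counted in the density signal;
#' they are carried along for the browser display only.
#'
#' @param genomes A FASTA path, a [genome_sequence()], or a list of them.
#' @param zfp57 A `ZFP57`-class [motif_catalog()] or a catalog file path;
#'   `NULL` skips the ZFP57 track.
#' @param morph A `ZFBS_MORPH`-class [motif_catalog()] or a catalog file
#'   path.
#' @param params A [density_params()].
#' @param strands Scan both strands (default) or the forward strand only.
#' @param collapse Collapse composite-motif hits sharing a genomic
#'   footprint before clustering (default FALSE: every hit counts).
#' @param build Optional genome-build label carried into exported tracks.
#' @return An object of class `icr_scan`: list with `genomes` (data.frame
#'   `chrom, length`), `hits` (list `zfp57`, `zfbs_morph` of hit
#'   data.frames), `peaks` (a `density_peaks` data.frame across all
#'   chromosomes), `params`, `strands`, `build`, `call`.
#' @export
#' @examples
#' cat_m <- motif_catalog(c("ACGCGTCG", "TCGCGACG"), "ZFBS_MORPH")
#' g <- genome_sequence("chr1", paste(c(
#'   "TTATATAATTTAAT", "ACGCGTCG", "TATTAAATTA", "TCGCGACG",
#'   strrep("AT", 40)), collapse = ""))
#' res <- icr_scan(g, zfp57 = NULL, morph = cat_m)
#' res$peaks$n_hits
icr_scan <- function(genomes, zfp57 = NULL, morph, params = density_params(),
                     strands = c("both", "forward_only"), collapse = FALSE,
                     build = NULL) {
  strands <- match.arg(strands)
  if (is.character(genomes)) genomes <- read_fasta(genomes)
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  if (is.character(zfp57)) zfp57 <- load_catalog(zfp57, "ZFP57")
  if (is.character(morph)) morph <- load_catalog(morph, "ZFBS_MORPH")
  stopifnot(inherits(morph, "motif_catalog"))
  if (morph$motifs$motif_class[1] != "ZFBS_MORPH")
    stop("'morph' must be a ZFBS_MORPH catalog")

  zfp_hits <- if (!is.null(zfp57))
    combine_hits(scan_genome(genomes, zfp57, strands)) else empty_hits()
  morph_by_chrom <- scan_genome(genomes, morph, strands)
  peak_list <- lapply(morph_by_chrom, function(h) {
    if (collapse && nrow(h)) h <- collapse_cofootprint_hits(h)
    cluster_hits(h, params)
  })
  peaks <- do.call(rbind, peak_list)
  rownames(peaks) <- NULL
  class(peaks) <- c("density_peaks", "data.frame")
  attr(peaks, "params") <- params

  structure(list(
    genomes = data.frame(
      chrom = vapply(genomes, function(g) g$chrom, character(1)),
      length = vapply(genomes, function(g) g$length, integer(1)),
      stringsAsFactors = FALSE),
    hits = list(zfp57 = zfp_hits, zfbs_morph = combine_hits(morph_by_chrom)),
    peaks = peaks, params = params, strands = strands, build = build,
    call = match.call()),
    class = "icr_scan")
}

#' @export
print.icr_scan <- function(x, ...) {
  cat(sprintf("<icr_scan>%s %d chromosome(s), %s bp total\n",
              if (!is.null(x$build)) paste0(" [", x$build, "]") else "",
              nrow(x$genomes), format(sum(x$genomes$length), big.mark = ",")))
  cat(sprintf("  ZFP57 hits: %d | ZFBS-morph overlap hits: %d (%s strand)\n",
              nrow(x$hits$zfp57), nrow(x$hits$zfbs_morph),
              if (x$strands == "both") "both" else "forward"))
  tiers <- table(factor(x$peaks$tier, levels = names(x$params$tier_thresholds)))
  cat(sprintf("  density peaks (window %d bp): %d [%s]\n",
              x$params$window_w, nrow(x$peaks),
              paste(sprintf("%s %d", names(tiers), tiers), collapse = ", ")))
  invisible(x)
}

#' @export
summary.icr_scan <- function(object, ...) {
  per_chrom <- do.call(rbind, lapply(seq_len(nrow(object$genomes)), function(i) {
    ch <- object$genomes$chrom[i]
    data.frame(chrom = ch, length = object$genomes$length[i],
               zfp57_hits = sum(object$hits$zfp57$chrom == ch),
               morph_hits = sum(object$hits$zfbs_morph$chrom == ch),
               peaks = sum(object$peaks$chrom == ch),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_chrom = per_chrom,
                 tiers = table(factor(object$peaks$tier,
                                      levels = names(object$params$tier_thresholds))),
                 params = object$params),
            class = "summary.icr_scan")
}

#' @export
print.summary.icr_scan <- function(x, ...) {
  cat("Per-chromosome counts:\n")
  print.data.frame(x$per_chrom, row.names = FALSE)
  cat("\nPeak tiers:\n")
  print(x$tiers)
  print(x$params)
  invisible(x)
}

#' Plot the peak landscape of a scan
#'
#' One panel per chromosome: composite-motif hit positions as a rug along
#' the axis, and each density peak as a vertical bar whose height is the
#' number of overlaps it covers — a base-graphics rendering of the
#' browser's density-plot track.
#'
#' @param x An [icr_scan()] result.
#' @param chroms Chromosomes to draw (default: all with at least one hit).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.icr_scan <- function(x, chroms = NULL, ...) {
  hits <- x$hits$zfbs_morph
  chroms <- chroms %||% unique(hits$chrom)
  if (length(chroms) == 0L) {
    warning("nothing to plot: no composite-motif hits")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(length(chroms), 1L),
                       mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    L <- x$genomes$length[x$genomes$chrom == ch]
    pk <- x$peaks[x$peaks$chrom == ch, , drop = FALSE]
    ymax <- max(c(pk$n_hits, 2L))
    graphics::plot(NA, xlim = c(0, L), ylim = c(0, ymax + 0.5),
                   xlab = "position (bp)", ylab = "overlaps in peak",
                   main = ch)
    hh <- hits[hits$chrom == ch, , drop = FALSE]
    if (nrow(hh)) graphics::rug(hh$start, ticksize = 0.03)
    if (nrow(pk))
      graphics::rect(pk$start, 0, pk$end, pk$n_hits,
                     col = "firebrick", border = NA)
  }
  invisible(x)
}
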