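# Panel benchmark: per-locus found/missed status of called peaks against a
# curated set of reference ICR/gDMR intervals, plus overall sensitivity.

#' Read a reference ICR panel
#'
#' Two dialects: headerless BED4 (`chrom start end locus_name`), or TSV
#' with a header naming at least `locus_name`, `chrom`, `start`, `end`
#' (optional `species_note` and `flag` columns; loci flagged `A`
#' (ambiguous) or `C` (comment) in published tables can be excluded at
#' evaluation time). Coordinates are 0-based half-open.
#'
#' @param path Panel file path.
#' @return A data.frame with columns `locus_name`, `chrom`, `start`, `end`,
#'   `species_note`, `flag`.
#' @export
read_icr_panel <- function(path) {
  if (!file.exists(path)) input_error("panel file not found: %s", path)
  first <- readLines(path, n = 1L)
  f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
  # dialect detection: a numeric 2nd field means headerless BED4
  headered <- length(f1) >= 4L && is.na(suppressWarnings(as.integer(f1[2])))
  if (!headered) {
    d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(d) < 4L) input_error("%s: BED4 panel needs 4 columns", path)
    d <- d[, 1:4]
    names(d) <- c("chrom", "start", "end", "locus_name")
  } else {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    need <- c("locus_name", "chrom", "start", "end")
    if (!all(need %in% names(d)))
      input_error("%s: panel TSV must have columns %s", path,
                  paste(need, collapse = ", "))
  }
  if (is.null(d$species_note)) d$species_note <- ""
  if (is.null(d$flag)) d$flag <- ""
  d <- d[, c("locus_name", "chrom", "start", "end", "species_note", "flag")]
  if (anyDuplicated(d$locus_name))
    input_error("%s: duplicate locus_name(s): %s", path,
                paste(unique(d$locus_name[duplicated(d$locus_name)]),
                      collapse = ", "))
  if (any(d$start >= d$end)) input_error("%s: panel interval with start >= end", path)
  d
}

tier_rank <- function(tier, thresholds = density_params()$tier_thresholds) {
  match(tier, names(thresholds))
}

#' Score called peaks against a reference ICR panel
#'
#' A locus is found (`Y`) iff some peak of tier at least `min_tier`
#' overlaps its interval by at least `min_overlap` bases; the overlap
#' criterion is deliberately permissive (>= 1 bp by default) because
#' correspondence between density peaks and reference ICRs is judged on the
#' browser, not by containment rules.
#'
#' @param peaks A [cluster_hits()] result (any number of chromosomes,
#'   rbind-ed).
#' @param panel A panel data.frame from [read_icr_panel()] (or with the
#'   same columns).
#' @param min_tier Lowest tier that counts, default `"candidate"` (all
#'   peaks).
#' @param min_overlap Minimal overlap in bases, default 1.
#' @param exclude_flags Loci whose `flag` is in this set are dropped before
#'   scoring (e.g. `c("A", "C")`); default keeps everything.
#' @return An object of class `icr_benchmark`: list with `per_locus`
#'   (data.frame `locus_name, chrom, start, end, status, best_peak_n_hits`),
#'   `n_found`, `n_total`, `sensitivity`.
#' @export
evaluate_against_panel <- function(peaks, panel, min_tier = "candidate",
                                   min_overlap = 1L, exclude_flags = character()) {
  thresholds <- attr(peaks, "params")$tier_thresholds %||%
    density_params()$tier_thresholds
  if (!min_tier %in% names(thresholds))
    stop(sprintf("unknown tier '%s'", min_tier))
  panel <- panel[!(panel$flag %in% setdiff(exclude_flags, "")), , drop = FALSE]
  if (nrow(panel) == 0L) stop("panel is empty after flag exclusion")
  use <- peaks[tier_rank(peaks$tier, thresholds) >=
                 tier_rank(min_tier, thresholds), , drop = FALSE]
  if (nrow(use) > 0L && !any(use$chrom %in% panel$chrom))
    warning("no chromosome names shared between peaks and panel; no locus can be found")

  status <- rep("N", nrow(panel))
  best <- rep(NA_integer_, nrow(panel))
  if (nrow(use) > 0L) {
    for (ch in unique(panel$chrom)) {
      pi <- which(panel$chrom == ch)
      qi <- which(use$chrom == ch)
      if (length(qi) == 0L) next
      tr <- IRanges::IRanges(panel$start[pi] + 1L, panel$end[pi])
      pk <- IRanges::IRanges(use$start[qi] + 1L, use$end[qi])
      ov <- IRanges::findOverlaps(tr, pk, minoverlap = as.integer(min_overlap))
      for (i in unique(S4Vectors::queryHits(ov))) {
        js <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
        status[pi[i]] <- "Y"
        best[pi[i]] <- max(use$n_hits[qi[js]])
      }
    }
  }
  per_locus <- data.frame(locus_name = panel$locus_name, chrom = panel$chrom,
                          start = panel$start, end = panel$end,
                          status = status, best_peak_n_hits = best,
                          stringsAsFactors = FALSE)
  n_found <- sum(status == "Y")
  structure(list(per_locus = per_locus, n_found = n_found,
                 n_total = nrow(panel),
                 sensitivity = n_found / nrow(panel),
                 min_tier = min_tier),
            class = "icr_benchmark")
}

#' @export
print.icr_benchmark <- function(x, ...) {
  cat(sprintf("<icr_benchmark> %d / %d reference loci found (sensitivity %.3f; min tier %s)\n",
              x$n_found, x$n_total, x$sensitivity, x$min_tier))
  invisible(x)
}

#' Write a benchmark report TSV
#'
#' One row per locus (`locus, chrom, start, end, status, best_peak_n_hits`)
#' followed by a `# sensitivity:` summary line.
#'
#' @param result An [evaluate_against_panel()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(result, path) {
  stopifnot(inherits(result, "icr_benchmark"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("locus_name", "chrom", "start", "end", "status",
                     "best_peak_n_hits"), collapse = "\t"), con)
  d <- result$per_locus
  writeLines(sprintf("%s\t%s\t%d\t%d\t%s\t%s", d$locus_name, d$chrom,
                     d$start, d$end, d$status,
                     ifelse(is.na(d$best_peak_n_hits), ".",
                            as.character(d$best_peak_n_hits))), con)
  writeLines(sprintf("# sensitivity: %d/%d = %.4f", result$n_found,
                     result$n_total, result$sensitivity), con)
  invisible(path)
}
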