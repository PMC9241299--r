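# Exact-match double-strand scanning of chromosomes for catalog motifs.
#
# Hits are plain data.frames (one row per occurrence) with 0-based half-open
# coordinates. Matching is strict: an N in the genome never matches any
# motif base, so assembly gaps are scanned through but can never hit.

hit_columns <- c("chrom", "start", "end", "strand", "motif_id",
                 "motif_class", "matched_seq")

empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), motif_id = character(),
             motif_class = character(), matched_seq = character(),
             stringsAsFactors = FALSE)
}

sort_hits <- function(hits) {
  # strand order fixed as + before -, independent of locale collation
  hits[order(hits$start, hits$end, hits$motif_id,
             match(hits$strand, c("+", "-"))), , drop = FALSE]
}

#' Scan one chromosome for all catalog motifs
#'
#' Reports every exact occurrence of every motif in `catalog` on the
#' chromosome. With `strands = "both"` (the default) the reverse complement
#' of each motif is also searched and reported as a `-` strand hit;
#' `matched_seq` is always the forward-strand genomic substring. A motif
#' equal to its own reverse complement yields a single `+` hit per position.
#' Overlapping and nested occurrences are all reported; nothing is
#' deduplicated at this stage (see [collapse_cofootprint_hits()]).
#'
#' @param genome A [genome_sequence()].
#' @param catalog A [motif_catalog()].
#' @param strands `"both"` or `"forward_only"`. Both strands are scanned by
#'   default: the composite elements are strand-agnostic CpG-rich motifs and
#'   browser tracks display strandless positions.
#' @return A data.frame of hits with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `motif_id`, `motif_class`,
#'   `matched_seq`, sorted by `(start, end, motif_id, strand)`.
#' @export
#' @examples
#' g <- genome_sequence("chr1", "TGCCGCAAGCGGCA")
#' scan_chromosome(g, motif_catalog("TGCCGC", "ZFP57"))
scan_chromosome <- function(genome, catalog, strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  stopifnot(inherits(genome, "genome_sequence"), inherits(catalog, "motif_catalog"))
  if (nrow(catalog$motifs) == 0L) stop("empty catalog")
  subject <- Biostrings::DNAString(genome$seq)
  out <- vector("list", nrow(catalog$motifs))
  for (i in seq_len(nrow(catalog$motifs))) {
    m <- catalog$motifs[i, ]
    pieces <- list()
    if (nchar(m$sequence) <= genome$length) {
      fwd <- Biostrings::start(
        Biostrings::matchPattern(m$sequence, subject, fixed = TRUE))
      if (length(fwd))
        pieces$fwd <- data.frame(
          chrom = genome$chrom, start = fwd - 1L,
          end = fwd - 1L + nchar(m$sequence), strand = "+",
          motif_id = m$id, motif_class = m$motif_class,
          matched_seq = m$sequence, stringsAsFactors = FALSE)
      rc <- revcomp(m$sequence)
      if (strands == "both" && rc != m$sequence) {
        rev <- Biostrings::start(
          Biostrings::matchPattern(rc, subject, fixed = TRUE))
        if (length(rev))
          pieces$rev <- data.frame(
            chrom = genome$chrom, start = rev - 1L,
            end = rev - 1L + nchar(m$sequence), strand = "-",
            motif_id = m$id, motif_class = m$motif_class,
            matched_seq = rc, stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- if (length(pieces)) do.call(rbind, pieces) else NULL
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  sort_hits(hits)
}

#' Scan a set of chromosomes
#'
#' Applies [scan_chromosome()] to each chromosome independently; results
#' never span chromosome boundaries.
#'
#' @param genomes A list of [genome_sequence()] objects (or a single one).
#' @inheritParams scan_chromosome
#' @return A named list, chromosome id -> hit data.frame, in input order.
#' @export
scan_genome <- function(genomes, catalog, strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  ids <- vapply(genomes, function(g) g$chrom, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate chromosome id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  res <- lapply(genomes, scan_chromosome, catalog = catalog, strands = strands)
  names(res) <- ids
  res
}

#' Combine per-chromosome hit lists into one data.frame
#'
#' @param hits_by_chrom The list returned by [scan_genome()].
#' @return One hit data.frame, chromosomes in input order.
#' @export
combine_hits <- function(hits_by_chrom) {
  if (length(hits_by_chrom) == 0L) return(empty_hits())
  hits <- do.call(rbind, hits_by_chrom)
  rownames(hits) <- NULL
  hits
}
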