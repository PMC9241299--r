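#' Construct a genome sequence record
#'
#' A `genome_sequence` is the package's in-memory representation of one
#' chromosome (or contig): an identifier plus a normalized DNA string over
#' the alphabet `{A, C, G, T, N}`. All coordinates elsewhere in the package
#' are 0-based half-open against this string; conversion to other
#' conventions happens only when writing browser tracks.
#'
#' @param chrom Non-empty chromosome identifier.
#' @param seq DNA string; it is passed through [normalize_sequence()].
#' @return An object of class `genome_sequence` with fields `chrom`, `seq`
#'   and `length`.
#' @seealso [read_fasta()], [write_fasta()]
#' @export
#' @examples
#' g <- genome_sequence("chr1", "acgtACGT")
#' g$length
genome_sequence <- function(chrom, seq) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) || !nzchar(chrom))
    stop("'chrom' must be a single non-empty string")
  seq <- normalize_sequence(seq)
  structure(
    list(chrom = chrom, seq = seq, length = nchar(seq)),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  head <- substr(x$seq, 1L, 60L)
  if (x$length > 60L) head <- paste0(head, "...")
  cat(sprintf("<genome_sequence> %s (%s bp)\n  %s\n",
              x$chrom, format(x$length, big.mark = ","), head))
  invisible(x)
}

#' Normalize a raw DNA string
#'
#' Uppercases the input, preserves `A/C/G/T/N`, and maps IUPAC ambiguity
#' codes (`R Y S W K M B D H V`) to `N` with a warning reporting how many
#' bases were masked. Any other character is an error naming the offending
#' character and its 0-based position. Soft-masked (lowercase) bases are
#' simply uppercased: repeat-masked sequence is scanned like any other.
#'
#' @param raw A character string.
#' @return The normalized DNA string over `{A,C,G,T,N}`.
#' @export
#' @examples
#' normalize_sequence("acgt")
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("'raw' must be a single character string")
  up <- toupper(raw)
  bad <- regexpr("[^ACGTNRYSWKMBDHV]", up)
  if (bad != -1L)
    stop(sprintf("illegal character '%s' at position %d (0-based)",
                 substr(up, bad, bad), as.integer(bad) - 1L))
  n_amb <- nchar(up) - nchar(gsub("[RYSWKMBDHV]", "", up))
  if (n_amb > 0L) {
    warning(sprintf("mapped %d IUPAC ambiguity base(s) to N", n_amb))
    up <- chartr("RYSWKMBDHV", "NNNNNNNNNN", up)
  }
  up
}

#' Reverse-complement a DNA string
#'
#' Strict alphabet `{A,C,G,T,N}`; `N` maps to `N`. Used for double-strand
#' scanning and for planting motifs in either orientation.
#'
#' @param seq DNA string.
#' @return The reverse complement.
#' @export
#' @examples
#' revcomp("ACGT")  # palindrome
revcomp <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("'seq' must be a single character string")
  if (!nzchar(seq)) return("")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1L)
    stop(sprintf("illegal character '%s' at position %d (0-based)",
                 substr(seq, bad, bad), as.integer(bad) - 1L))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read chromosome sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped, possibly soft-masked) multi-record FASTA
#' file and returns one [genome_sequence()] per record, in file order.
#' The record id is the first whitespace-delimited token of the header.
#' Sequences are normalized via [normalize_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return A list of `genome_sequence` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) input_error("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) input_error("no records in FASTA file: %s", path)
  if (!startsWith(first, ">"))
    input_error("not a FASTA file (first line does not start with '>'): %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) input_error("no records in FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    input_error("duplicate record id(s) in %s: %s", path,
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(seq_along(set), function(i) genome_sequence(ids[i], as.character(set[[i]])))
}

#' Write genome sequences to FASTA
#'
#' Writes standard multi-record FASTA with 60-column line wrapping, the
#' inverse of [read_fasta()] on `(chrom, seq)` pairs.
#'
#' @param genomes A single `genome_sequence` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  if (length(genomes) == 0L) stop("nothing to write")
  seqs <- vapply(genomes, function(g) g$seq, character(1))
  ids <- vapply(genomes, function(g) g$chrom, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
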