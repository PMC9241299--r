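#' Construct a motif catalog
#'
#' A catalog is an ordered set of exact DNA motifs belonging to one of two
#' classes: plain ZFP57 binding sites (`"ZFP57"`), or ZFBS-morph overlaps
#' (`"ZFBS_MORPH"`) — composite elements in which a ZFP57 site overlaps a
#' CpG-rich MLL morpheme. Only the `ZFBS_MORPH` class feeds the density
#' computation; `ZFP57` hits are displayed as their own track.
#'
#' Motif sequences are exact strings over `{A,C,G,T}` (no ambiguity codes:
#' scanning is exact-match, not degenerate). Motifs of different lengths may
#' coexist in one catalog, since composite elements vary in length.
#'
#' @param sequences Character vector of motif sequences (uppercased on input).
#' @param motif_class `"ZFP57"` or `"ZFBS_MORPH"`.
#' @param ids Optional motif labels; defaults to `m1`, `m2`, ...
#' @param name Catalog name.
#' @param provenance Free-text source note.
#' @return An object of class `motif_catalog`.
#' @export
#' @examples
#' motif_catalog("TGCCGC", "ZFP57")
motif_catalog <- function(sequences, motif_class = c("ZFP57", "ZFBS_MORPH"),
                          ids = NULL, name = "catalog", provenance = "") {
  motif_class <- match.arg(motif_class)
  if (length(sequences) == 0L) stop("a catalog must contain at least one motif")
  sequences <- toupper(sequences)
  if (is.null(ids)) ids <- paste0("m", seq_along(sequences))
  if (length(ids) != length(sequences)) stop("'ids' and 'sequences' lengths differ")
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    if (nchar(s) < 4L)
      stop(sprintf("motif '%s' (%s): length %d < 4", ids[i], s, nchar(s)))
    if (grepl("[^ACGT]", s))
      stop(sprintf("motif '%s' (%s): sequences must contain only A/C/G/T", ids[i], s))
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate motif id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (anyDuplicated(sequences))
    stop(sprintf("duplicate motif sequence(s) within class %s: %s", motif_class,
                 paste(unique(sequences[duplicated(sequences)]), collapse = ", ")))
  structure(
    list(name = name, provenance = provenance,
         motifs = data.frame(id = ids, sequence = sequences,
                             motif_class = motif_class,
                             stringsAsFactors = FALSE)),
    class = "motif_catalog"
  )
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("<motif_catalog> %s: %d %s motif(s), lengths %s\n",
              x$name, nrow(x$motifs), x$motifs$motif_class[1],
              paste(range(nchar(x$motifs$sequence)), collapse = "-")))
  if (nzchar(x$provenance)) cat("  source:", x$provenance, "\n")
  invisible(x)
}

#' Load a motif catalog from a file
#'
#' Accepts either plain text (one motif per line, optionally
#' `id<TAB>sequence`) or FASTA (header supplies the id). Lines starting with
#' `#` and blank lines are ignored. Sequences are uppercased and validated;
#' ids default to `m1`, `m2`, ... in file order when absent.
#'
#' The package ships two default catalog files under `extdata/`:
#' `zfp57.txt` (the hexameric ZFP57 recognition site, TGCCGC) and
#' `zfbs_morph_overlaps_synthetic.txt`, a synthetic stand-in set of
#' CpG-rich composites. The published composite-element list is not
#' redistributed here; for real analyses supply your own transcription of it
#' as an ordinary catalog file.
#'
#' @param path Catalog file path.
#' @param motif_class `"ZFP57"` or `"ZFBS_MORPH"`.
#' @param name Catalog name; defaults to the file base name.
#' @return A [motif_catalog()].
#' @export
load_catalog <- function(path, motif_class = c("ZFP57", "ZFBS_MORPH"),
                         name = NULL) {
  motif_class <- match.arg(motif_class)
  if (!file.exists(path)) input_error("catalog file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) input_error("empty catalog file: %s", path)

  if (startsWith(lines[1], ">")) {
    # FASTA dialect: header token = id, wrapped sequence lines allowed
    starts <- which(startsWith(lines, ">"))
    if (starts[1] != 1L)
      input_error("%s line %d: sequence before first FASTA header", path, lineno[1])
    ends <- c(starts[-1] - 1L, length(lines))
    ids <- sub("\\s.*$", "", sub("^>", "", lines[starts]))
    seqs <- vapply(seq_along(starts), function(i) {
      if (starts[i] + 1L > ends[i])
        input_error("%s line %d: FASTA record '%s' has no sequence",
                    path, lineno[starts[i]], ids[i])
      paste(lines[(starts[i] + 1L):ends[i]], collapse = "")
    }, character(1))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- character(length(parts))
    seqs <- character(length(parts))
    for (i in seq_along(parts)) {
      p <- trimws(parts[[i]])
      p <- p[nzchar(p)]
      if (length(p) == 1L) {
        ids[i] <- paste0("m", i); seqs[i] <- p
      } else if (length(p) == 2L) {
        ids[i] <- p[1]; seqs[i] <- p[2]
      } else {
        input_error("%s line %d: expected 'sequence' or 'id<TAB>sequence'",
                    path, lineno[i])
      }
    }
  }
  seqs <- toupper(seqs)
  bad <- grep("[^ACGT]", seqs)
  if (length(bad)) {
    bad_line <- if (startsWith(lines[1], ">")) lineno[starts[bad[1]]] else lineno[bad[1]]
    input_error("%s line %d: illegal character in motif sequence '%s'",
                path, bad_line, seqs[bad[1]])
  }
  if (anyDuplicated(seqs))
    input_error("%s: duplicate motif sequence '%s' within class %s",
                path, seqs[duplicated(seqs)][1], motif_class)
  motif_catalog(seqs, motif_class, ids = ids,
                name = name %||% basename(path),
                provenance = path)
}

#' Write a motif catalog to a plain-text file
#'
#' One `id<TAB>sequence` line per motif, reloadable by [load_catalog()].
#'
#' @param catalog A [motif_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "motif_catalog"))
  writeLines(paste(catalog$motifs$id, catalog$motifs$sequence, sep = "\t"), path)
  invisible(path)
}
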