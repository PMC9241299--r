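# UCSC custom-track writers: BED and bedGraph files with track lines.
#
# The three-track display mirrors the browser figures of the original
# analysis: ZFP57 sites in dense mode, ZFBS-morph overlaps in pack mode,
# and the density peaks in full mode. All emitted coordinates are 0-based
# half-open (the native BED/bedGraph convention), lines end with "\n", and
# integer formatting is fixed, so output is byte-deterministic.

#' Describe a custom track
#'
#' @param name Track name (no tabs or newlines).
#' @param description Track description; defaults to `name`.
#' @param visibility One of `"dense"`, `"pack"`, `"full"`.
#' @param color RGB triple, each 0-255. Default black.
#' @param db_label Optional genome-build label (e.g. `"bosTau8"`), recorded
#'   for provenance; not emitted in the track line.
#' @return An object of class `track_spec`.
#' @export
track_spec <- function(name, description = name,
                       visibility = c("dense", "pack", "full"),
                       color = c(0L, 0L, 0L), db_label = NULL) {
  visibility <- match.arg(visibility)
  for (s in c(name, description))
    if (grepl("[\t\n]", s)) stop("track name/description must not contain tab or newline")
  if (!nzchar(name)) stop("track name must be non-empty")
  color <- as.integer(color)
  if (length(color) != 3L || any(is.na(color)) || any(color < 0L | color > 255L))
    stop("'color' must be an RGB triple in 0-255")
  structure(list(name = name, description = description,
                 visibility = visibility, color = color, db_label = db_label),
            class = "track_spec")
}

#' Render a UCSC track line
#'
#' Field order is fixed: `type` (bedGraph only), `name`, `description`,
#' `visibility`, `color`.
#'
#' @param spec A [track_spec()].
#' @param track_type `"bed"` (type attribute omitted) or `"bedGraph"`.
#' @return A single-line character string.
#' @export
#' @examples
#' render_track_line(track_spec("ZFP57", visibility = "dense"))
render_track_line <- function(spec, track_type = c("bed", "bedGraph")) {
  track_type <- match.arg(track_type)
  stopifnot(inherits(spec, "track_spec"))
  type_field <- if (track_type == "bedGraph") "type=bedGraph " else ""
  sprintf('track %sname="%s" description="%s" visibility=%s color=%s',
          type_field, spec$name, spec$description, spec$visibility,
          paste(spec$color, collapse = ","))
}

#' Parse a UCSC track line back into its attributes
#'
#' Inverse of [render_track_line()] for round-trip checking: tokenizes
#' `key=value` pairs, honouring double-quoted values.
#'
#' @param line A track line string.
#' @return Named list of attribute strings.
#' @export
parse_track_line <- function(line) {
  if (!startsWith(line, "track ")) stop("not a track line")
  rest <- substr(line, 7L, nchar(line))
  m <- gregexpr('([A-Za-z]+)=("[^"]*"|[^ ]+)', rest)[[1]]
  toks <- regmatches(rest, list(m))[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    gsub('^"|"$', "", v)
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  vals
}

check_bounds <- function(chrom, end, chrom_sizes) {
  if (is.null(chrom_sizes)) return(invisible())
  sz <- chrom_sizes$size[match(chrom, chrom_sizes$chrom)]
  over <- which(!is.na(sz) & end > sz)
  if (length(over))
    stop(sprintf("record end %d exceeds declared length %d of chromosome %s",
                 end[over[1]], sz[over[1]], chrom[over[1]]))
  invisible()
}

write_track_file <- function(track_line, body, path) {
  con <- file(path, open = "wb")   # binary: "\n" endings on every platform
  on.exit(close(con))
  writeLines(c(track_line, body), con, sep = "\n")
  invisible(path)
}

#' Write motif hits as a BED6 custom track
#'
#' Columns: chrom, start, end, name (`motif_id`), score 0, strand.
#'
#' @param hits Hit data.frame (any number of chromosomes).
#' @param path Output path.
#' @param spec A [track_spec()]; defaults to a dense black track named
#'   `"hits"`.
#' @param chrom_sizes Optional data.frame `(chrom, size)` for bounds checks.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, spec = track_spec("hits"),
                           chrom_sizes = NULL) {
  hits <- hits[order(hits$chrom, hits$start, hits$end, hits$motif_id), , drop = FALSE]
  check_bounds(hits$chrom, hits$end, chrom_sizes)
  body <- if (nrow(hits)) sprintf("%s\t%d\t%d\t%s\t0\t%s", hits$chrom,
                                  hits$start, hits$end, hits$motif_id,
                                  hits$strand) else character()
  write_track_file(render_track_line(spec, "bed"), body, path)
}

#' Write density peaks as a BED5 custom track
#'
#' Columns: chrom, start, end, name (tier label), score (`n_hits`).
#'
#' @param peaks A [cluster_hits()] result.
#' @inheritParams write_hits_bed
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path,
                            spec = track_spec("peaks", visibility = "full"),
                            chrom_sizes = NULL) {
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  check_bounds(peaks$chrom, peaks$end, chrom_sizes)
  body <- if (nrow(peaks)) sprintf("%s\t%d\t%d\t%s\t%d", peaks$chrom,
                                   peaks$start, peaks$end, peaks$tier,
                                   peaks$n_hits) else character()
  write_track_file(render_track_line(spec, "bed"), body, path)
}

#' Write the peak density signal as a bedGraph custom track
#'
#' One line per peak, `chrom<TAB>start<TAB>end<TAB>value`, where the value
#' is either the cluster size (`n_hits`, default) or the maximal
#' single-window count (`max_window_count`).
#'
#' @param peaks A [cluster_hits()] result.
#' @param mode Which peak score becomes the track value.
#' @inheritParams write_hits_bed
#' @return `path`, invisibly.
#' @export
write_density_bedgraph <- function(peaks, path,
                                   spec = track_spec("density", visibility = "full"),
                                   mode = c("n_hits", "max_window_count"),
                                   chrom_sizes = NULL) {
  mode <- match.arg(mode)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  check_bounds(peaks$chrom, peaks$end, chrom_sizes)
  body <- if (nrow(peaks)) sprintf("%s\t%d\t%d\t%d", peaks$chrom, peaks$start,
                                   peaks$end, peaks[[mode]]) else character()
  write_track_file(render_track_line(spec, "bedGraph"), body, path)
}

#' Read back a BED/bedGraph custom-track file
#'
#' Skips the leading track line and returns the data records; used for
#' round-trip checks and by the command-line density step.
#'
#' @param path Track file path.
#' @return List with `track` (parsed attributes, or NULL if no track line)
#'   and `records` (data.frame; columns named by dialect: BED6 hit files
#'   give `chrom,start,end,name,score,strand`, BED5 peak files
#'   `chrom,start,end,name,score`, bedGraph `chrom,start,end,value`).
#' @export
read_track_file <- function(path) {
  if (!file.exists(path)) input_error("track file not found: %s", path)
  lines <- readLines(path)
  track <- NULL
  if (length(lines) && startsWith(lines[1], "track ")) {
    track <- parse_track_line(lines[1])
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(list(track = track, records = data.frame()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1L) input_error("%s: ragged column counts", path)
  cols <- switch(as.character(ncol),
                 "4" = c("chrom", "start", "end", "value"),
                 "5" = c("chrom", "start", "end", "name", "score"),
                 "6" = c("chrom", "start", "end", "name", "score", "strand"),
                 input_error("%s: unsupported column count %d", path, ncol))
  rec <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(rec) <- cols
  for (nm in intersect(c("start", "end", "score", "value"), cols))
    rec[[nm]] <- as.integer(rec[[nm]])
  list(track = track, records = rec)
}

#' Export the full three-track browser bundle
#'
#' Writes the custom-track files of the standard display: `zfp57.bed`
#' (dense), `zfbs_morph.bed` (pack), `density.bedgraph` and `peaks.bed`
#' (full). Records are sorted by `(chrom, start)`; each file starts with its
#' track line.
#'
#' @param hits_by_class Named list with elements `zfp57` and `zfbs_morph`,
#'   each a hit data.frame (possibly empty).
#' @param peaks A [cluster_hits()] result (rbind-ed across chromosomes).
#' @param out_dir Output directory (created if needed).
#' @param specs Optional named list of [track_spec()]s overriding the
#'   defaults, keyed `zfp57`, `zfbs_morph`, `density`, `peaks`.
#' @param chrom_sizes Optional data.frame `(chrom, size)`; records past a
#'   declared chromosome end raise an error.
#' @return Named character vector of the four file paths.
#' @export
export_bundle <- function(hits_by_class, peaks, out_dir, specs = list(),
                          chrom_sizes = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  defaults <- list(
    zfp57 = track_spec("ZFP57", "ZFP57 binding sites", "dense"),
    zfbs_morph = track_spec("ZFBS_morph", "ZFBS-morph overlaps", "pack",
                            color = c(0L, 0L, 180L)),
    density = track_spec("density", "ZFBS-morph overlap density",
                         "full", color = c(180L, 0L, 0L)),
    peaks = track_spec("peaks", "density peaks", "full",
                       color = c(180L, 0L, 0L)))
  for (k in names(specs)) defaults[[k]] <- specs[[k]]
  paths <- c(
    zfp57 = file.path(out_dir, "zfp57.bed"),
    zfbs_morph = file.path(out_dir, "zfbs_morph.bed"),
    density = file.path(out_dir, "density.bedgraph"),
    peaks = file.path(out_dir, "peaks.bed"))
  write_hits_bed(hits_by_class$zfp57 %||% empty_hits(), paths["zfp57"],
                 defaults$zfp57, chrom_sizes)
  write_hits_bed(hits_by_class$zfbs_morph %||% empty_hits(), paths["zfbs_morph"],
                 defaults$zfbs_morph, chrom_sizes)
  write_density_bedgraph(peaks, paths["density"], defaults$density,
                         chrom_sizes = chrom_sizes)
  write_peaks_bed(peaks, paths["peaks"], defaults$peaks, chrom_sizes)
  paths
}
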