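# Shared fixtures and independent oracles. Oracles are deliberately naive
# (substring equality, per-base window scans) and never call the scanner or
# the clustering code they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A catalog of random distinct motifs with the given lengths.
random_catalog <- function(lengths, motif_class = "ZFBS_MORPH") {
  repeat {
    seqs <- vapply(lengths, random_dna, character(1), gc = 0.5)
    if (!anyDuplicated(seqs)) return(motif_catalog(seqs, motif_class))
  }
}

# Naive reverse complement, independent of the package's revcomp().
naive_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# Brute-force scanner oracle: test every substring of every motif length
# against every motif and its reverse complement by string equality.
# Returns a data.frame(start, end, strand, motif_id) (0-based half-open).
oracle_scan <- function(seq, catalog, strands = "both") {
  rows <- list()
  for (i in seq_len(nrow(catalog$motifs))) {
    m <- catalog$motifs$sequence[i]
    id <- catalog$motifs$id[i]
    k <- nchar(m)
    if (k > nchar(seq)) next
    rc <- naive_revcomp(m)
    for (p in 0:(nchar(seq) - k)) {
      sub <- substr(seq, p + 1, p + k)
      if (sub == m) {
        rows[[length(rows) + 1]] <-
          data.frame(start = p, end = p + k, strand = "+", motif_id = id,
                     stringsAsFactors = FALSE)
      } else if (strands == "both" && sub == rc && rc != m) {
        rows[[length(rows) + 1]] <-
          data.frame(start = p, end = p + k, strand = "-", motif_id = id,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), motif_id = character(),
                      stringsAsFactors = FALSE))
  d <- do.call(rbind, rows)
  d <- d[order(d$start, d$end, d$motif_id, match(d$strand, c("+", "-"))), ]
  rownames(d) <- NULL
  d
}

# Per-base window-scan clustering oracle. For every window anchor p it
# collects the set of starts in [p, p + W); windows holding >= 2 starts are
# "dense". Transitively merging dense windows that share a member yields the
# oracle clusters; clusters below min_hits are dropped. This walks every
# anchor position literally, so keep the coordinate range small.
oracle_cluster_members <- function(starts, W, min_hits = 2L) {
  if (length(starts) == 0L) return(list())
  starts <- sort(starts)
  members <- lapply(0:max(starts), function(p) starts[starts >= p & starts < p + W])
  members <- members[vapply(members, length, integer(1)) >= 2L]
  clusters <- list()
  for (m in members) {
    joined <- FALSE
    for (k in seq_along(clusters)) {
      if (length(intersect(clusters[[k]], m))) {
        clusters[[k]] <- sort(union(clusters[[k]], m))
        joined <- TRUE
        break
      }
    }
    if (!joined) clusters[[length(clusters) + 1]] <- m
  }
  # one more pass to merge chains discovered out of order
  repeat {
    merged <- FALSE
    if (length(clusters) > 1) for (a in 1:(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        if (length(intersect(clusters[[a]], clusters[[b]]))) {
          clusters[[a]] <- sort(union(clusters[[a]], clusters[[b]]))
          clusters[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters <- clusters[vapply(clusters, length, integer(1)) >= min_hits]
  clusters[order(vapply(clusters, min, numeric(1)))]
}

# Hits data.frame from bare start positions of a fixed-length motif.
hits_from_starts <- function(starts, chrom = "chr1", len = 6L,
                             motif_class = "ZFBS_MORPH") {
  n <- length(starts)
  data.frame(chrom = rep(chrom, n), start = as.integer(starts),
             end = as.integer(starts + len), strand = rep("+", n),
             motif_id = rep("m1", n), motif_class = rep(motif_class, n),
             matched_seq = rep(strrep("A", len), n),
             stringsAsFactors = FALSE)
}

# Peaks data.frame built directly from intervals (for benchmark tests).
peaks_from_intervals <- function(starts, ends, chrom = "chr1",
                                 n_hits = 2L, tier = "candidate") {
  d <- data.frame(chrom = rep_len(chrom, length(starts)),
                  start = as.integer(starts),
                  end = as.integer(ends),
                  n_hits = as.integer(rep_len(n_hits, length(starts))),
                  max_window_count = as.integer(rep_len(n_hits, length(starts))),
                  tier = rep_len(tier, length(starts)),
                  stringsAsFactors = FALSE)
  class(d) <- c("density_peaks", "data.frame")
  attr(d, "params") <- density_params()
  d
}
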