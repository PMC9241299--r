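test_that("single-motif examples: forward, reverse, N-block, palindrome", {
  cat1 <- motif_catalog("TGCCGC", "ZFP57")

  h <- scan_chromosome(genome_sequence("c", "TGCCGC"), cat1)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 6L)
  expect_equal(h$strand, "+")
  expect_equal(h$matched_seq, "TGCCGC")

  h <- scan_chromosome(genome_sequence("c", "GCGGCA"), cat1)
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_equal(h$matched_seq, "GCGGCA")

  expect_equal(nrow(scan_chromosome(genome_sequence("c", "TGNCGC"), cat1)), 0)

  # a self-reverse-complement motif yields one "+" hit per position
  pal <- motif_catalog("ACGCGT", "ZFBS_MORPH")
  h <- scan_chromosome(genome_sequence("c", "AACGCGTA"), pal)
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")

  # motif longer than the chromosome: zero hits, not an error
  long <- motif_catalog("ACGTACGTAC", "ZFP57")
  expect_equal(nrow(scan_chromosome(genome_sequence("c", "ACGT"), long)), 0)

  expect_error(scan_chromosome(genome_sequence("c", "ACGT"), "not a catalog"))
})

test_that("overlapping and nested occurrences are all reported", {
  cat1 <- motif_catalog("AAAA", "ZFBS_MORPH")
  h <- scan_chromosome(genome_sequence("c", "AAAAAA"), cat1)
  expect_equal(h$start, 0:2)
})

test_that("hit set equals the naive all-substrings oracle on random inputs", {
  set.seed(202)
  for (rep in 1:50) {
    seq <- random_dna(2000, gc = runif(1, 0.3, 0.7))
    cat1 <- random_catalog(sample(4:10, sample(1:6, 1), replace = TRUE))
    g <- genome_sequence("c", seq)
    for (strands in c("both", "forward_only")) {
      got <- scan_chromosome(g, cat1, strands)
      want <- oracle_scan(seq, cat1, strands)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$strand, want$strand)
      expect_equal(got$motif_id, want$motif_id)
    }
  }
})

test_that("hits never extend past the chromosome end and sort deterministically", {
  set.seed(7)
  for (rep in 1:10) {
    seq <- random_dna(500)
    cat1 <- random_catalog(c(4L, 4L, 6L))
    g <- genome_sequence("c", seq)
    h <- scan_chromosome(g, cat1)
    if (nrow(h)) {
      expect_true(all(h$start >= 0 & h$end <= g$length & h$start < h$end))
      expect_true(all(h$end - h$start ==
                        nchar(cat1$motifs$sequence[match(h$motif_id,
                                                         cat1$motifs$id)])))
      o <- order(h$start, h$end, h$motif_id, match(h$strand, c("+", "-")))
      expect_equal(o, seq_len(nrow(h)))
    }
    expect_identical(scan_chromosome(g, cat1), h)  # determinism
  }
})

test_that("strand symmetry: scanning the reverse-complemented chromosome mirrors hits", {
  set.seed(303)
  for (rep in 1:10) {
    seq <- random_dna(1500)
    cat1 <- random_catalog(c(5L, 6L, 7L))
    g <- genome_sequence("c", seq)
    grc <- genome_sequence("c", revcomp(seq))
    h <- scan_chromosome(g, cat1)
    hrc <- scan_chromosome(grc, cat1)
    expect_equal(nrow(h), nrow(hrc))
    if (nrow(h)) {
      mirrored <- data.frame(start = g$length - h$end, end = g$length - h$start,
                             motif_id = h$motif_id,
                             strand = ifelse(h$strand == "+", "-", "+"),
                             stringsAsFactors = FALSE)
      selfrc <- vapply(cat1$motifs$sequence[match(h$motif_id, cat1$motifs$id)],
                       function(m) m == revcomp(m), logical(1))
      mirrored$strand[selfrc] <- "+"
      o <- order(mirrored$start, mirrored$end, mirrored$motif_id,
                 match(mirrored$strand, c("+", "-")))
      mirrored <- mirrored[o, ]
      expect_equal(hrc$start, mirrored$start)
      expect_equal(hrc$end, mirrored$end)
      expect_equal(hrc$strand, mirrored$strand)
      expect_equal(hrc$motif_id, mirrored$motif_id)
    }
  }
})

test_that("mean hit count of a 6-mer on uniform background matches expectation", {
  # i.i.d. uniform ACGT, L = 100,000: a non-self-overlapping, non-palindromic
  # 6-mer has expected both-strand count 2 * (L - 5) / 4^6
  set.seed(404)
  cat6 <- motif_catalog("TGCCGA", "ZFP57")  # no self-overlap, not palindromic
  L <- 100000L
  n_rep <- 100L
  counts <- vapply(seq_len(n_rep), function(i) {
    nrow(scan_chromosome(genome_sequence("c", random_dna(L, gc = 0.5)), cat6))
  }, numeric(1))
  expected <- 2 * (L - 5) / 4^6
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 5 * se)
})

test_that("scan_genome keeps chromosomes independent and ordered", {
  cat1 <- motif_catalog("TGCCGC", "ZFP57")
  g1 <- genome_sequence("chrA", "ATATATATAT")
  g2 <- genome_sequence("chrB", "AATGCCGCTT")
  res <- scan_genome(list(g1, g2), cat1)
  expect_equal(names(res), c("chrA", "chrB"))
  expect_equal(nrow(res$chrA), 0)
  expect_equal(nrow(res$chrB), 1)
  # per-chromosome scans equal independent scans
  expect_identical(res$chrB, scan_chromosome(g2, cat1))
  expect_error(scan_genome(list(g1, g1), cat1), "duplicate chromosome")
  # combine preserves order and total count
  all_hits <- combine_hits(res)
  expect_equal(nrow(all_hits), 1)
  expect_equal(all_hits$chrom, "chrB")
})
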