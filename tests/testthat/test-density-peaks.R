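test_that("window_count uses half-open [p, p + W) and matches a naive count", {
  p850 <- density_params()
  expect_equal(window_count(c(100, 500), 100, p850), 2)
  expect_equal(window_count(c(100, 950), 100, p850), 1)
  expect_error(window_count(c(500, 100), 0, p850), "sorted")
  set.seed(99)
  for (rep in 1:100) {
    starts <- sort(sample.int(5000, sample(0:30, 1)))
    p <- sample.int(5000, 1)
    W <- sample(c(100L, 850L), 1)
    naive <- sum(vapply(starts, function(s) s >= p && s < p + W, logical(1)))
    expect_equal(window_count(starts, p, density_params(window_w = W)), naive)
  }
})

test_that("isolated overlaps are suppressed; empty input gives no peaks", {
  p850 <- density_params()
  expect_equal(nrow(cluster_hits(hits_from_starts(integer()), p850)), 0)
  expect_equal(nrow(cluster_hits(hits_from_starts(2000), p850)), 0)
})

test_that("hand-enumerated clusters: pair kept, distant pair dropped", {
  # starts 100 and 500 co-window (gap 400 <= 849); 2000 and 2900 do not
  # (gap 900 > 849), so both become isolated and are dropped
  pk <- cluster_hits(hits_from_starts(c(100, 500, 2000, 2900)), density_params())
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 506L)
  expect_equal(pk$n_hits, 2L)
  expect_equal(pk$max_window_count, 2L)
  expect_equal(pk$tier, "candidate")
  expect_equal(nrow(pk$members[[1]]), 2)
})

test_that("chained cluster: n_hits counts the chain, max_window_count one window", {
  # consecutive gaps of 800 chain under W = 850, but no single 850-base
  # window holds all three starts
  pk <- cluster_hits(hits_from_starts(c(0, 800, 1600)), density_params())
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 0L)
  expect_equal(pk$end, 1606L)
  expect_equal(pk$n_hits, 3L)
  expect_equal(pk$max_window_count, 2L)
  expect_equal(pk$tier, "robust")
})

test_that("a compact 7-hit cluster gives one very robust peak", {
  # mirrors the structure of the 7-overlap cattle KvDMR1 peak
  starts <- c(0, 90, 200, 310, 420, 510, 594)  # all within a 600-base span
  pk <- cluster_hits(hits_from_starts(starts + 5000), density_params())
  expect_equal(nrow(pk), 1)
  expect_equal(pk$n_hits, 7L)
  expect_equal(pk$max_window_count, 7L)
  expect_equal(pk$tier, "very_robust")
})

test_that("input validation: unsorted, multi-chromosome, wrong class", {
  p850 <- density_params()
  h <- hits_from_starts(c(500, 100))
  expect_error(cluster_hits(h, p850), "sorted")
  h2 <- hits_from_starts(c(100, 500))
  h2$chrom <- c("chr1", "chr2")
  expect_error(cluster_hits(h2, p850), "single chromosome")
  h3 <- hits_from_starts(c(100, 500), motif_class = "ZFP57")
  expect_error(cluster_hits(h3, p850), "ZFBS_MORPH")
})

test_that("clustering equals the per-base window-scan oracle on random inputs", {
  set.seed(515)
  for (rep in 1:25) {
    W <- sample(c(200L, 850L), 1)
    n <- sample(2:25, 1)
    starts <- sort(sample.int(20000, n))
    pk <- cluster_hits(hits_from_starts(starts), density_params(window_w = W))
    want <- oracle_cluster_members(starts, W)
    expect_equal(nrow(pk), length(want))
    if (nrow(pk)) {
      got_members <- lapply(pk$members, function(m) m$start)
      expect_equal(got_members, want)
      # every peak obeys the consecutive-gap bound and the tier rule
      for (i in seq_len(nrow(pk))) {
        s <- got_members[[i]]
        if (length(s) > 1) expect_true(all(diff(s) <= W - 1))
        expect_gte(pk$max_window_count[i], 2L)
        expect_lte(pk$max_window_count[i], pk$n_hits[i])
      }
      # peaks are sorted and non-overlapping
      if (nrow(pk) > 1) expect_true(all(pk$start[-1] >= head(pk$end, -1)))
    }
  }
})

test_that("tier mapping follows the published reliability language", {
  expect_equal(assign_tier(2), "candidate")    # could be true or false positive
  expect_equal(assign_tier(3), "robust")       # more reliable
  expect_equal(assign_tier(4), "very_robust")
  expect_equal(assign_tier(7), "very_robust")
  expect_equal(assign_tier(c(2, 3, 7)), c("candidate", "robust", "very_robust"))
  expect_error(assign_tier(1), ">= 2")
  # thresholds configurable and monotone: raising very_robust demotes a 4-peak
  tt <- c(candidate = 2L, robust = 3L, very_robust = 6L)
  expect_equal(assign_tier(4, tt), "robust")
  expect_equal(assign_tier(6, tt), "very_robust")
  expect_error(density_params(tier_thresholds = c(a = 3L, b = 2L)), "increasing")
})

test_that("peak member sets are nested within larger-window peaks", {
  # universal property: the co-window relation only gains pairs as W grows,
  # so every W-peak's member set sits inside some W'-peak (W' > W)
  set.seed(616)
  for (rep in 1:15) {
    starts <- sort(sample.int(30000, sample(5:30, 1)))
    h <- hits_from_starts(starts)
    pks <- lapply(c(200L, 850L, 2000L),
                  function(W) cluster_hits(h, density_params(window_w = W)))
    for (k in 1:2) {
      small <- pks[[k]]; big <- pks[[k + 1]]
      for (i in seq_len(nrow(small))) {
        m <- small$members[[i]]$start
        inside <- vapply(seq_len(nrow(big)), function(j)
          all(m %in% big$members[[j]]$start), logical(1))
        expect_true(any(inside))
      }
    }
  }
})

test_that("peak count is non-increasing in W on chained fixtures", {
  # chained fixture: every hit is already clustered at the smallest window
  # (no isolated hits anywhere), so growing the window can only merge peaks,
  # never mint new ones from rescued singletons
  set.seed(626)
  for (rep in 1:15) {
    n_groups <- sample(2:6, 1)
    starts <- integer()
    pos <- 0L
    for (g in seq_len(n_groups)) {
      size <- sample(2:5, 1)
      gaps <- sample(20:190, size - 1, replace = TRUE)   # chain at W = 200
      starts <- c(starts, pos + cumsum(c(0L, gaps)))
      pos <- max(starts) + sample(300:3000, 1)           # group separation
    }
    h <- hits_from_starts(starts)
    counts <- vapply(c(200L, 850L, 2000L), function(W)
      nrow(cluster_hits(h, density_params(window_w = W))), integer(1))
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[1], n_groups)
  }
})

test_that("raising min_hits never creates or grows a peak", {
  set.seed(717)
  for (rep in 1:10) {
    starts <- sort(sample.int(20000, sample(5:25, 1)))
    h <- hits_from_starts(starts)
    pk2 <- cluster_hits(h, density_params(min_hits = 2))
    pk3 <- cluster_hits(h, density_params(min_hits = 3))
    expect_lte(nrow(pk3), nrow(pk2))
    # every min_hits=3 peak exists identically among the min_hits=2 peaks
    if (nrow(pk3)) {
      key2 <- paste(pk2$start, pk2$end, pk2$n_hits)
      expect_true(all(paste(pk3$start, pk3$end, pk3$n_hits) %in% key2))
    }
  }
})

test_that("co-footprint collapse keeps the earliest/longest/lexicographic survivor", {
  h <- hits_from_starts(c(100, 100), len = 6L)
  h$motif_id <- c("b", "a")
  h <- h[order(h$start, h$end, h$motif_id), ]
  out <- collapse_cofootprint_hits(h)
  expect_equal(nrow(out), 1)
  expect_equal(out$motif_id, "a")

  disjoint <- hits_from_starts(c(0, 100, 200))
  expect_equal(collapse_cofootprint_hits(disjoint), disjoint)

  # randomized overlap sets against a naive interval-sweep oracle
  set.seed(818)
  for (rep in 1:30) {
    n <- sample(2:15, 1)
    start <- sort(sample.int(300, n, replace = TRUE))
    len <- sample(4:10, n, replace = TRUE)
    h <- data.frame(chrom = "c", start = start, end = start + len,
                    strand = "+", motif_id = sample(letters[1:4], n, TRUE),
                    motif_class = "ZFBS_MORPH", matched_seq = "X",
                    stringsAsFactors = FALSE)
    h <- h[order(h$start, h$end, h$motif_id), ]
    got <- collapse_cofootprint_hits(h)
    # oracle: build overlap components by transitive sweep, pick survivor
    comp <- integer(n); cid <- 0L; max_end <- -1L
    for (i in seq_len(n)) {
      if (h$start[i] >= max_end) { cid <- cid + 1L; max_end <- h$end[i] }
      else max_end <- max(max_end, h$end[i])
      comp[i] <- cid
    }
    surv <- do.call(rbind, lapply(split(h, comp), function(d) {
      d[order(d$start, -(d$end - d$start), d$motif_id), ][1, ]
    }))
    expect_equal(got$start, surv$start)
    expect_equal(got$end, surv$end)
    expect_equal(got$motif_id, surv$motif_id)
  }
})
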