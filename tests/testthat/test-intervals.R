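test_that("window_overlaps follows the extension rule at boundaries", {
  a <- g_intervals("chr1", 1000, 1200)
  expect_true(window_overlaps(a, g_intervals("chr1", 1400, 1500), w = 300))
  # gap of exactly 301 bp: one base beyond the window
  expect_false(window_overlaps(a, g_intervals("chr1", 1501, 1600), w = 300))
  # gap of exactly 300 bp: extended spans touch but do not intersect
  expect_false(window_overlaps(a, g_intervals("chr1", 1500, 1600), w = 300))
  expect_true(window_overlaps(a, g_intervals("chr1", 1499, 1600), w = 300))
  expect_false(window_overlaps(a, g_intervals("chr2", 1000, 1200), w = 300))
  # w = 0 reduces to plain half-open overlap: adjacency does not count
  expect_false(window_overlaps(a, g_intervals("chr1", 1200, 1300), w = 0))
  expect_true(window_overlaps(a, g_intervals("chr1", 1199, 1300), w = 0))
  expect_error(window_overlaps(a, a, w = -1), "non-negative")
})

test_that("window_overlaps is symmetric on random interval pairs", {
  set.seed(101)
  for (k in 1:200) {
    a <- random_intervals(1)
    b <- random_intervals(1)
    w <- sample(c(0L, 1L, 50L, 300L), 1)
    expect_identical(window_overlaps(a, b, w), window_overlaps(b, a, w))
  }
})

test_that("overlap_any handles edge cases and rejects unsorted input", {
  q <- g_intervals("chr1", 0, 100)
  expect_identical(overlap_any(q, q[0, ], w = 300), FALSE)
  q2 <- g_intervals(c("chr1", "chr1"), c(0, 500), c(100, 600))
  s <- g_intervals("chr1", 350, 400)
  expect_identical(overlap_any(q2, s, w = 300), c(TRUE, TRUE))
  unsorted <- q2[c(2, 1), ]
  expect_error(overlap_any(unsorted, s), "sorted")
})

test_that("overlap_any agrees with the all-pairs brute-force oracle", {
  set.seed(202)
  total_checked <- 0
  for (k in 1:60) {
    q <- random_intervals(sample(5:25, 1))
    s <- random_intervals(sample(0:25, 1))
    w <- sample(c(0L, 10L, 300L), 1)
    expect_identical(overlap_any(q, s, w), oracle_overlap_any(q, s, w))
    total_checked <- total_checked + nrow(q)
  }
  expect_gte(total_checked, 600)
})

test_that("consensus keeps exactly the anchor peaks supported everywhere", {
  pk <- g_intervals("chr1", 5000, 5400)
  r1 <- make_collection(pk, "r1")
  r2 <- make_collection(pk, "r2")
  cons <- consensus_peaks(list(r1, r2), w = 300)
  expect_equal(cons$intervals[, c("chrom", "start", "end")],
               pk[, c("chrom", "start", "end")])

  # peak private to replicate 1 of 3 is excluded
  priv <- g_intervals(c("chr1", "chr1"), c(5000, 50000), c(5400, 50400))
  cons2 <- consensus_peaks(list(make_collection(priv, "r1"),
                                make_collection(pk, "r2"),
                                make_collection(pk, "r3")), w = 300)
  expect_equal(nrow(cons2$intervals), 1)
  expect_equal(cons2$intervals$start, 5000)

  # single replicate returns itself unchanged
  cons3 <- consensus_peaks(list(r1), w = 300)
  expect_identical(cons3$intervals, r1$intervals)

  expect_error(consensus_peaks(list()), "at least one")
  r_bad <- peak_collection(pk, "x", mark = "5hmC", condition = "control",
                           paradigm = "CSDS", age = "3mo")
  expect_error(consensus_peaks(list(r1, r_bad)), "mismatched")
})

test_that("consensus recovers planted shared peaks against brute force", {
  set.seed(303)
  shared <- random_intervals(50, chroms = "chrA", max_width = 300)
  reps <- lapply(1:3, function(r) {
    private <- g_intervals("chrB", seq(1000, 20000, by = 1000) + r * 100,
                           seq(1000, 20000, by = 1000) + r * 100 + 200)
    make_collection(sort_intervals(rbind(shared, private)),
                    sprintf("r%d", r))
  })
  cons <- consensus_peaks(reps, w = 300)
  # brute-force check of every anchor peak against every replicate
  anchor <- reps[[1]]$intervals
  expected <- anchor[
    oracle_overlap_any(anchor, reps[[2]]$intervals, 300) &
      oracle_overlap_any(anchor, reps[[3]]$intervals, 300), ]
  expect_equal(cons$intervals$start, expected$start)
  expect_true(all(shared$start %in% cons$intervals$start))
})

test_that("consensus is anchor-monotone: adding a replicate never adds peaks", {
  set.seed(404)
  for (k in 1:25) {
    reps <- lapply(1:4, function(r)
      make_collection(random_intervals(30), sprintf("r%d", r)))
    n3 <- length(consensus_peaks(reps[1:3], w = 300))
    n4 <- length(consensus_peaks(reps, w = 300))
    expect_lte(n4, n3)
  }
})

test_that("merge_intervals unions overlaps and preserves covered bases", {
  xs <- g_intervals(c("chr1", "chr1"), c(0, 50), c(100, 150))
  m <- merge_intervals(xs)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 150))
  expect_equal(nrow(merge_intervals(g_intervals(character(0), integer(0),
                                                integer(0)))), 0)

  set.seed(505)
  xs <- random_intervals(500, chroms = "chrA", genome_len = 5e4)
  m <- merge_intervals(xs, gap = 0)
  # output is sorted and non-overlapping
  expect_true(is_sorted_intervals(m))
  expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  # total covered bp equals the per-base mask oracle
  expect_equal(sum(m$end - m$start), oracle_covered_bases(xs, 5e4))
  expect_equal(covered_bases(xs), oracle_covered_bases(xs, 5e4))
})

test_that("interval constructor enforces its invariants", {
  expect_error(g_intervals("chr1", -1, 10), ">= 0")
  expect_error(g_intervals("chr1", 10, 10), "half-open")
  expect_error(g_intervals("", 0, 10), "non-empty")
  out <- g_intervals(c("chr2", "chr1"), c(5, 1), c(10, 4))
  expect_identical(out$chrom, c("chr1", "chr2"))
})

test_that("BED round trip preserves coordinates and ids", {
  xs <- g_intervals(c("chr1", "chr2"), c(0, 999), c(500, 2000),
                    id = c("pkA", "pkB"))
  path <- tempfile(fileext = ".bed")
  write_bed(xs, path)
  back <- read_peaks_bed(path)
  expect_equal(back[, c("chrom", "start", "end", "id")],
               xs[, c("chrom", "start", "end", "id")])
})
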