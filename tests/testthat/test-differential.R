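test_that("gained/lost calls follow presence/absence under the window", {
  stress <- make_collection(g_intervals("chr1", 5000, 5400), "s",
                            condition = "susceptible")
  empty <- make_collection(g_intervals(character(0), integer(0),
                                       integer(0)), "c")
  d <- call_differential(stress, empty, w = 300)
  expect_equal(nrow(d$gained$regions), 1)
  expect_equal(nrow(d$lost$regions), 0)

  same <- make_collection(stress$intervals, "c")
  d2 <- call_differential(stress, same, w = 300)
  expect_equal(nrow(d2$gained$regions), 0)
  expect_equal(nrow(d2$lost$regions), 0)

  bad <- peak_collection(stress$intervals, "x", mark = "5hmC",
                         condition = "control", paradigm = "CSDS",
                         age = "3mo")
  expect_error(call_differential(stress, bad), "mismatched")
})

test_that("random differential calls match the brute-force oracle and swap", {
  set.seed(606)
  for (k in 1:40) {
    s <- make_collection(random_intervals(sample(5:40, 1)), "s",
                         condition = "susceptible")
    c_ <- make_collection(random_intervals(sample(5:40, 1)), "c")
    w <- sample(c(0L, 300L), 1)
    d <- call_differential(s, c_, w = w)
    exp_gain <- s$intervals[!oracle_overlap_any(s$intervals, c_$intervals,
                                                w), ]
    exp_lost <- c_$intervals[!oracle_overlap_any(c_$intervals, s$intervals,
                                                 w), ]
    expect_equal(d$gained$regions$start, exp_gain$start)
    expect_equal(d$lost$regions$start, exp_lost$start)
    # swapping stress and control swaps gained and lost exactly
    dswap <- call_differential(
      peak_collection(c_$intervals, "c", "5mC", "susceptible", "CSDS",
                      "3mo"),
      peak_collection(s$intervals, "s", "5mC", "control", "CSDS", "3mo"),
      w = w)
    expect_equal(dswap$gained$regions$start, d$lost$regions$start)
    expect_equal(dswap$lost$regions$start, d$gained$regions$start)
    # no gained region may window-overlap any control peak
    expect_false(any(oracle_overlap_any(d$gained$regions, c_$intervals, w)))
  }
})

test_that("condition_specific performs windowed subtraction", {
  a <- differential_region_set(
    g_intervals(c("chr1", "chr1"), c(1000, 9000), c(1300, 9300)),
    direction = "gained")
  b <- differential_region_set(g_intervals("chr1", 9100, 9400),
                               direction = "gained")
  out <- condition_specific(a, b, w = 300)
  expect_equal(out$regions$start, 1000)
  expect_equal(nrow(condition_specific(a, a, w = 300)$regions), 0)
  # subtracting the empty set is the identity
  e <- differential_region_set(g_intervals(character(0), integer(0),
                                           integer(0)),
                               direction = "gained")
  expect_equal(condition_specific(a, e, w = 300)$regions$start,
               a$regions$start)
  wrongdir <- differential_region_set(b$regions, direction = "lost")
  expect_error(condition_specific(a, wrongdir), "direction")
})

test_that("condition_specific equals the brute-force subtraction oracle", {
  set.seed(707)
  for (k in 1:40) {
    a <- differential_region_set(random_intervals(sample(5:30, 1)),
                                 direction = "gained")
    b <- differential_region_set(random_intervals(sample(5:30, 1)),
                                 direction = "gained")
    out <- condition_specific(a, b, w = 300)
    keep <- !oracle_overlap_any(a$regions, b$regions, 300)
    expect_equal(out$regions$start, a$regions$start[keep])
  }
})

test_that("overlap_regions reports pairs and a bounded shared fraction", {
  a <- differential_region_set(random_intervals(0), direction = "gained")
  set.seed(808)
  r <- random_intervals(50)
  full <- differential_region_set(r, direction = "gained")
  self <- overlap_regions(full, full, w = 300)
  expect_equal(self$fraction_shared, 1.0)
  expect_true(is.na(overlap_regions(a, full, w = 300)$fraction_shared))

  disjoint <- differential_region_set(
    g_intervals("chrZ", r$start, r$end), direction = "gained")
  expect_equal(overlap_regions(full, disjoint, w = 300)$fraction_shared, 0)
})

test_that("a planted 90% overlap design is recovered exactly", {
  set.seed(909)
  base <- g_intervals("chrA", seq(1000, 200000, by = 1000),
                      seq(1000, 200000, by = 1000) + 200)[1:200, ]
  reused <- base[1:180, ]  # 90% of a-regions reused in b
  b_extra <- g_intervals("chrB", seq(1000, 30000, by = 1000),
                         seq(1000, 30000, by = 1000) + 200)
  a <- differential_region_set(base, direction = "gained")
  b <- differential_region_set(sort_intervals(rbind(reused, b_extra)),
                               direction = "gained")
  ov <- overlap_regions(a, b, w = 300)
  expect_equal(ov$fraction_shared, 0.90)
  expect_equal(ov$a_only, 20)
  # multi-mapped a-regions are still counted once in the fraction
  expect_lte(ov$fraction_shared, 1)
})

test_that("cross-mark overlap contracts: disjoint 0, identical 1, flags", {
  set.seed(111)
  r <- random_intervals(40)
  dmr <- differential_region_set(r, mark = "5mC", direction = "gained")
  dhmr_same <- differential_region_set(r, mark = "5hmC",
                                       direction = "lost")
  expect_equal(cross_mark_overlap(dmr, dhmr_same, w = 300)$fraction_shared,
               1.0)
  far <- differential_region_set(g_intervals("chrZ", r$start, r$end),
                                 mark = "5hmC", direction = "lost")
  expect_equal(cross_mark_overlap(dmr, far, w = 300)$fraction_shared, 0)
  same_dir <- differential_region_set(r, mark = "5hmC",
                                      direction = "gained")
  expect_warning(cross_mark_overlap(dmr, same_dir, w = 300),
                 "same-direction")
  expect_error(cross_mark_overlap(same_dir, dmr), "5mC")
})
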