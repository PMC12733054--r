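test_that("monomorphic fill assigns 1.0 and keeps informative/missing blocks", {
  blocks <- make_blocks("chr1", c(0, 100, 200), c(100, 200, 300))
  # block 2 has no parental polymorphism; block 3 is polymorphic but all code 0
  loci <- make_loci("chr1", c(10, 50, 210, 250),
                    list(RP = rep("AA", 4), DP = c("GG", "GG", "GG", "GG"),
                         I1 = c("AA", "AG", NA, NA)))
  poly <- find_polymorphic_loci(loci, "RP", "DP")
  track <- aggregate_to_blocks(code_individuals(loci, "I1", poly), poly, blocks)
  sig <- fill_monomorphic(track)
  expect_equal(unname(sig[, 1]), c(0.5, 1.0, NA))
  expect_equal(track$monomorphic, 2L)
})

test_that("a clean step signal yields exactly one breakpoint at the step", {
  x <- c(rep(1, 20), rep(0, 20))
  fs <- cbs_first_split(x)
  expect_equal(fs$i, 0L)
  expect_equal(fs$j, 20L)
  expect_true(is.infinite(fs$stat))
  expect_equal(cbs_segment(x), 20L)
})

test_that("constant and outlier signals yield no breakpoints", {
  expect_equal(cbs_segment(rep(1, 40)), integer(0))
  # single outlier: min_width = 5 forbids a one-block segment and every
  # permutation attains the same maximal statistic, so p = 1
  for (k in c(1, 8, 15, 30)) {
    x <- rep(1, 30)
    x[k] <- 0
    expect_equal(cbs_segment(x, n_perm = 200), integer(0))
  }
  expect_error(cbs_segment(c(1, Inf, 0)), "non-finite")
})

test_that("first split matches the brute-force oracle on random small signals", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(10:30, 1)
    mw <- sample(c(2L, 3L, 5L), 1)
    x <- round(rnorm(n, mean = rep(c(1, 0), each = ceiling(n / 2))[1:n], sd = 0.3), 3)
    got <- cbs_first_split(x, min_width = mw)
    want <- oracle_first_split(x, mw)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    if (is.finite(want$stat)) expect_equal(got$stat, want$stat, tolerance = 1e-8)
  }
})

test_that("interior donor arcs produce both boundaries", {
  x <- c(rep(1, 15), rep(0, 8), rep(1, 15))
  expect_equal(cbs_segment(x), c(15L, 23L))
})

test_that("cbs is deterministic under a fixed seed", {
  set.seed(55)
  x <- rnorm(60) + rep(c(0, 1.2, 0), times = c(20, 20, 20))
  b1 <- cbs_segment(x, n_perm = 500, seed = 17)
  b2 <- cbs_segment(x, n_perm = 500, seed = 17)
  expect_identical(b1, b2)
})

test_that("smoothing preserves opposite-state runs of at least min_width", {
  set.seed(77)
  for (rep in 1:5) {
    run <- sample(5:12, 1)
    flank <- sample(10:25, 2)
    x <- c(rep(1, flank[1]), rep(0, run), rep(1, flank[2]))
    x <- x + rnorm(length(x), sd = 0.05)
    x <- pmin(pmax(x, 0), 1)
    bp <- cbs_segment(x, n_perm = 500)
    seg <- finalize_segments(x, bp, make_blocks("chr1", seq_along(x) - 1, seq_along(x)))
    expect_true(any(seg$state == 2L))
    donor <- seg[seg$state == 2L, ]
    expect_true(any(donor$first_block <= flank[1] + 2 & donor$last_block >= flank[1] + run - 1))
  }
})

test_that("missing blocks are absorbed and keep genomic coordinates intact", {
  blocks <- make_blocks("chr1", 0:19 * 10, 1:20 * 10)
  sig <- c(rep(1, 8), NA, NA, rep(0, 10))
  bp <- cbs_segment(sig)
  seg <- finalize_segments(sig, bp, blocks)
  expect_equal(sum(seg$end - seg$start), 200)  # partition covers the chromosome
  expect_equal(seg$state, c(1L, 2L))
  expect_equal(nrow(seg), 2L)
})

test_that("segment medians, nearest-neighbor fill and merging follow the rules", {
  blocks <- make_blocks("chr1", 0:11 * 10, 1:12 * 10)
  sig <- c(1, 1, 0.9, NA, NA, NA, 0, 0.1, 0, 0.9, 0.8, 1)
  seg <- finalize_segments(sig, c(3L, 6L, 9L), blocks)
  # [1,1,0.9] median 1 -> state 1; all-missing takes left neighbor's state and
  # merges with it; [0,0.1,0] median 0 -> state 2; [0.9,0.8,1] -> state 1
  expect_equal(seg$state, c(1L, 2L, 1L))
  expect_equal(seg$last_block, c(6L, 9L, 12L))
  expect_equal(seg$median_value[2], 0)
  # two adjacent state-1 segments merge into one
  seg2 <- finalize_segments(c(1, 1, 0.9, 0.8, 0.85, 0.9), 3L,
                            make_blocks("chr1", 0:5 * 10, 1:6 * 10))
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$state, 1L)
})

test_that("breakpoint intervals sit on block boundaries between distinct states", {
  blocks <- make_blocks("chr1", 0:19 * 100, 1:20 * 100)
  sig <- c(rep(1, 10), rep(0, 10))
  seg <- finalize_segments(sig, cbs_segment(sig), blocks)
  bp <- call_breakpoints(seg, blocks)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$left_last_block, 10L)
  expect_equal(bp$right_first_block, 11L)
  expect_equal(bp$left_end, 1000L)
  expect_equal(bp$right_start, 1001L)
  # one uniform segment: no breakpoints
  seg1 <- finalize_segments(rep(1, 20), integer(0), blocks)
  expect_equal(nrow(call_breakpoints(seg1, blocks)), 0L)
})
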