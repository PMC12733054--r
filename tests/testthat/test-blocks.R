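block_fixture <- function(codes) {
  # one chromosome, 3 blocks of 100 bp, four loci per block
  blocks <- make_blocks("chr1", c(0, 100, 200), c(100, 200, 300))
  n <- length(codes)
  stopifnot(n == 12)
  pos <- c(10, 30, 50, 70, 110, 130, 150, 170, 210, 230, 250, 270)
  calls <- c("AA", "AG", "GG")[match(codes, c(1, 2, 0))]
  calls[codes == 0] <- NA
  loci <- make_loci("chr1", pos, list(RP = rep("AA", n), DP = rep("GG", n), I1 = calls))
  poly <- find_polymorphic_loci(loci, "RP", "DP")
  coded <- code_individuals(loci, "I1", poly)
  list(track = aggregate_to_blocks(coded, poly, blocks), blocks = blocks,
       coded = coded, poly = poly)
}

test_that("block aggregation tallies code-1/code-2 counts and proportions", {
  fx <- block_fixture(c(1, 1, 2, 1, 0, 0, 0, 0, 2, 2, 1, 0))
  tr <- fx$track
  expect_equal(unname(tr$n_recurrent[, 1]), c(3L, 0L, 1L))
  expect_equal(unname(tr$n_donor[, 1]), c(1L, 0L, 2L))
  expect_equal(unname(tr$p[, 1]), c(0.75, NA, 1 / 3))
  # conservation: block counts sum to genome-wide code counts
  expect_equal(sum(tr$n_recurrent), sum(fx$coded == 1L))
  expect_equal(sum(tr$n_donor), sum(fx$coded == 2L))
  # loci outside all blocks are an error
  small <- make_blocks("chr1", 0, 150)
  expect_error(aggregate_to_blocks(fx$coded, fx$poly, small), "outside")
})

test_that("state assignment uses a strict threshold and preserves missing", {
  fx <- block_fixture(c(1, 1, 2, 1, 0, 0, 0, 0, 2, 2, 1, 2))
  tr <- assign_block_states(fx$track, 0.5)
  expect_equal(unname(tr$state[, 1]), c(1L, 0L, 2L))  # 0.75 > 0.5; NA -> 0; 0.25 <= 0.5
  # p exactly at the threshold is unrecovered ("exceeded" is strict)
  fx2 <- block_fixture(c(1, 1, 2, 2, 1, 1, 1, 1, 2, 2, 2, 2))
  tr2 <- assign_block_states(fx2$track, 0.5)
  expect_equal(unname(tr2$state[, 1]), c(2L, 1L, 2L))
})

test_that("htbr is the state-1 share of non-missing blocks", {
  fx <- block_fixture(c(1, 1, 1, 1, 0, 0, 0, 0, 2, 2, 2, 1))
  tr <- assign_block_states(fx$track, 0.5)
  expect_equal(unname(htbr(tr, "I1")), 1 / 2)  # states 1, 0, 2
  # raising the threshold never increases the number of state-1 blocks
  fx3 <- block_fixture(c(1, 1, 2, 1, 2, 1, 1, 2, 1, 2, 2, 2))
  ns <- vapply(seq(0.1, 0.9, by = 0.1), function(t) {
    sum(assign_block_states(fx3$track, t)$state == 1L)
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("htbr equals the block mean of p when every block is pure", {
  fx <- block_fixture(c(1, 1, 1, 1, 2, 2, 2, 2, 1, 1, 1, 1))
  tr <- assign_block_states(fx$track, 0.5)
  expect_equal(unname(htbr(tr, "I1")), mean(tr$p[, 1]))
  all_missing <- block_fixture(rep(0, 12))
  expect_error(htbr(assign_block_states(all_missing$track, 0.5), "I1"),
               "all blocks missing")
})

test_that("calibration separates clean extreme classes at every threshold", {
  # error-free: recovered-class blocks all p = 1, unrecovered all p = 0
  sim <- simulate_population(sim_config(n_chrom = 4, chrom_lengths = rep(5e5, 4),
                                        genetic_lengths = rep(50, 4), n_blocks = 80,
                                        n_ind = 12, error_rate = 0, missing_rate = 0,
                                        seed = 9))
  poly <- find_polymorphic_loci(sim$loci, "RP", "DP")
  coded <- code_individuals(sim$loci, sim$samples, poly)
  track <- aggregate_to_blocks(coded, poly, sim$blocks)
  rec <- chromosome_snp_recovery(coded, poly)
  # keep only fully pure individual-chromosomes so the classes are degenerate
  rec <- rec[rec$recovery %in% c(0, 1), ]
  skip_if(length(unique(rec$recovery)) < 2)  # needs both extremes in the draw
  cal <- calibrate_threshold(track, rec)
  expect_true(all(cal$rate_recovered == 1))
  expect_true(all(cal$rate_unrecovered == 0))
  expect_equal(cal$selected, cal$grid[1])  # first plateau point
  # curves at 0.5 equal the fraction of blocks with p > 0.5 by definition
  expect_equal(cal$rate_recovered[cal$grid == 0.5],
               unname(cal$frac_above_05["recovered"]))
})

test_that("calibration refuses to run without both extreme classes", {
  fx <- block_fixture(rep(1, 12))
  rec <- data.frame(sample = "I1", chrom = "chr1", recovery = 1)
  expect_error(calibrate_threshold(fx$track, rec), "default threshold 0.5")
})
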