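test_that("config validation rejects impossible settings", {
  expect_error(sim_config(error_rate = 1.2), "rates")
  expect_error(sim_config(generation = 3), "generation")
  expect_error(sim_config(n_ind = 0), "population size")
  cfg <- sim_config(n_chrom = 2, chrom_lengths = c(2e6, 1e6))
  expect_equal(cfg$genetic_lengths, c(1.4, 0.7))  # 0.7 cM per Mb default
})

test_that("BC1 and BC2 cohorts center on the classical recovery expectations", {
  # truth-only runs: allele-weighted RP fraction, 0.75 (BC1) / 0.875 (BC2)
  cfg1 <- sim_config(n_ind = 400, error_rate = 0, missing_rate = 0, seed = 21)
  s1 <- simulate_population(cfg1, make_genotypes = FALSE)
  f1 <- s1$truth$rp_fraction
  expect_lt(abs(mean(f1) - 0.75), 3 * sd(f1) / sqrt(length(f1)))
  expect_equal(mean(s1$truth$rp_background), 2 * mean(f1) - 1)  # het counts 0 vs 1/2
  cfg2 <- sim_config(n_ind = 400, generation = 2, error_rate = 0,
                     missing_rate = 0, seed = 22)
  s2 <- simulate_population(cfg2, make_genotypes = FALSE)
  f2 <- s2$truth$rp_fraction
  # BC2 fractions are conditional on the shared BC1 parent: the cohort mean
  # must match 1 - parent_donor / (4 * genome), which itself centers on 0.875
  genome <- sum(cfg2$chrom_lengths)
  cond_mean <- 1 - s2$truth$parent_donor_len / (4 * genome)
  expect_lt(abs(mean(f2) - cond_mean), 3 * sd(f2) / sqrt(length(f2)))
  expect_lt(abs(cond_mean - 0.875), 0.05)  # parent donor close to 1/2 genome
  expect_gt(min(c(f1, f2)), 0)
  expect_lte(max(c(f1, f2)), 1)
})

test_that("crossover counts follow the genetic map (Poisson rate check)", {
  cfg <- sim_config(n_chrom = 1, chrom_lengths = 2e6, genetic_lengths = 200,
                    n_blocks = 10, n_ind = 2000, error_rate = 0,
                    missing_rate = 0, seed = 23)
  sim <- simulate_population(cfg, make_genotypes = FALSE)
  k <- tabulate(factor(sim$truth$crossovers$sample, levels = sim$samples),
                nbins = cfg$n_ind)
  se <- sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - 2), 3 * se)  # 2 Morgans -> mean 2 crossovers
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_chrom = 2, chrom_lengths = c(1e6, 5e5), n_blocks = 30,
                    n_ind = 5, seed = 31)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$loci, b$loci)
  expect_identical(a$truth, b$truth)
  expect_identical(a$blocks, b$blocks)
})

test_that("donor segments are disjoint and parents fully informative", {
  sim <- simulate_population(sim_config(n_chrom = 2, chrom_lengths = c(1e6, 8e5),
                                        n_blocks = 30, n_ind = 8, seed = 33))
  d <- sim$truth$donor
  for (s in unique(d$sample)) {
    for (c in unique(d$chrom)) {
      dd <- d[d$sample == s & d$chrom == c, ]
      if (nrow(dd) > 1) expect_true(all(dd$start[-1] >= dd$end[-nrow(dd)]))
    }
  }
  expect_true(all(sim$loci$RP != sim$loci$DP))
  hom <- function(g) substr(g, 1, 1) == substr(g, 2, 2)
  expect_true(all(hom(sim$loci$RP) & hom(sim$loci$DP)))
})

test_that("block-resolution truth matches a per-bp rasterization oracle", {
  for (seed in c(41, 42, 43)) {
    sim <- simulate_population(sim_config(n_chrom = 2, chrom_lengths = c(1500, 900),
                                          genetic_lengths = c(150, 100),
                                          n_blocks = 24, snps_per_block = 3,
                                          n_ind = 6, error_rate = 0,
                                          missing_rate = 0, seed = seed),
                               make_genotypes = FALSE)
    tm <- truth_metrics(sim, sim$blocks, mode = "length")
    unrec <- attr(tm, "unrecovered")
    for (s in colnames(unrec)) {
      expect_equal(unname(unrec[, s]),
                   oracle_rasterize(sim$truth$donor, sim$blocks, s))
    }
  }
})

test_that("truth metrics report block-resolution WGBR and fragment counts", {
  # hand-built truth: donor covering blocks 5-10 of a 20-block chromosome
  blocks <- make_blocks("chr1", 0:19 * 100, 1:20 * 100)
  truth <- list(donor = data.frame(sample = "X", chrom = "chr1",
                                   start = 400, end = 1000),
                rp_fraction = c(X = 0.85))
  tm <- truth_metrics(truth, blocks, mode = "length")
  expect_equal(tm$true_wgbr, 0.7)
  expect_equal(tm$n_fragments, 1)
  none <- truth_metrics(list(donor = truth$donor[0, ], rp_fraction = c(Y = 1)),
                        blocks, mode = "length")
  expect_equal(none$true_wgbr, 1)
  expect_equal(none$n_fragments, 0)
})
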