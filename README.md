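# g2hscan

Haplotype-block assessment of recurrent-parent genome recovery in
marker-assisted backcross breeding.

## The problem

Backcross (BC) breeding introgresses a donor trait into an elite recurrent
parent (RP) while recovering the RP genome as fast as possible. Counting
recovered point markers (the classical background recovery rate) ignores
chromosomal structure: two plants with the same marker-level recovery can
carry very different residual donor fragments, and scattered small fragments
are much harder to purge in later generations than a few consolidated ones
(linkage drag). `g2hscan` implements a block-scanning strategy that converts
high-density SNP genotypes into haplotype-block states, smooths them into
chromosomal segments, and scores every individual at three resolutions plus a
fragment-architecture index:

- **PRPG** (SNP level): `PRPG = A / B x 100%`, where `A` is the number of
  RP-homozygous coded loci and `B` the number of non-missing coded loci.
  Coding per locus: RP-homozygous = 1, parental heterozygous = 2, everything
  else (missing, donor-homozygous, off-type) = 0.
- **HTBR** (block level): `HTBR = NS_HTP / N_HTP`, the share of non-missing
  haplotype blocks whose recovered-SNP proportion exceeds the threshold
  (default 0.5, derivable from chromosomal extremes with
  `calibrate_threshold()`).
- **WGBR** (segment level): `WGBR = LS_HTP / L_HTP`, the length-weighted
  recovered share after circular binary segmentation (CBS; alpha = 0.001,
  undo.SD = 1.5, min.width = 5) with median segment states. Individuals with
  `WGBR >= 95%` are flagged high-recovery.
- **CFDI**: `CFDI = 0.5 N* + 0.5 P*` with
  `N* = (N - N_min) / (N_max - N_min)` the cohort-standardized unrecovered
  fragment count and `P*` the mean per-chromosome unrecovered length
  proportion. Lower is better: fewer, more consolidated donor fragments.

Boundaries between adjacent segments of different state are reported as
candidate recombination breakpoints. A ground-truthed backcross simulator
(Poisson crossover model, genotyping error, missingness) provides validation
data and powers the test suite.

## Worked example

```r
library(g2hscan)

cfg <- sim_config(n_chrom = 3, chrom_lengths = c(3e6, 2e6, 1.5e6),
                  genetic_lengths = c(120, 90, 70), n_blocks = 90,
                  snps_per_block = 5, n_ind = 5, error_rate = 0.02,
                  missing_rate = 0.05, seed = 42)
sim <- simulate_population(cfg)
res <- run_pipeline(sim$loci, sim$blocks, rp = "RP", dp = "DP")
res$report
#>    sample  prpg   htbr   wgbr n_fragments   cfdi high_recovery
#> 1 BC1_001 20.65 0.1667 0.1491           4 0.6589         FALSE
#> 2 BC1_002 24.88 0.2667 0.2617           4 0.6405         FALSE
#> 3 BC1_003 36.50 0.3444 0.3664           3 0.3574         FALSE
#> 4 BC1_004 40.64 0.4000 0.3772           5 0.8011         FALSE
#> 5 BC1_005 53.47 0.5222 0.5406           4 0.4919         FALSE
```

Each row is one BC1 individual: `prpg` is the SNP-count recovery in percent,
`htbr` and `wgbr` the block-count and length-weighted recovered proportions,
and `cfdi` the fragment-distribution index relative to this cohort. BC1_005
leads the ranking (highest WGBR); among the rest, BC1_003 combines a decent
WGBR with the lowest CFDI (few, consolidated donor fragments), while BC1_004
has slightly higher WGBR but the worst CFDI — exactly the distinction the
index is built to expose:

```r
res$ranking[, c("rank", "sample", "wgbr", "cfdi", "n_fragments")]
#>   rank  sample   wgbr   cfdi n_fragments
#> 1    1 BC1_005 0.5406 0.4919           4
#> 2    2 BC1_004 0.3772 0.8011           5
#> 3    3 BC1_003 0.3664 0.3574           3
```

Against the simulator's block-resolution ground truth, the recovered WGBR of
this noisy toy cohort deviates by at most 2.4 percentage points (0 for three
of the five individuals):

```r
tm <- truth_metrics(sim, sim$blocks, mode = "snp", poly = res$poly)
abs(res$report$wgbr - tm$true_wgbr[match(res$report$sample, tm$sample)])
#> [1] 0.0065 0.0000 0.0000 0.0241 0.0000
```

With `out_dir =` set, `run_pipeline()` writes `summary.tsv`, `segments.tsv`
(1-based inclusive coordinates), `breakpoints.tsv`, `fragments.tsv`,
`ranking.tsv` and a reproducibility manifest. A thin command-line wrapper
lives at `inst/cli/g2h.R` with `run`, `simulate`, `calibrate` and `rank`
subcommands.

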