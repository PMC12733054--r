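---
title: "Haplotype-block scanning for backcross background recovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block scanning for backcross background recovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`g2hscan` assesses how much of the recurrent parent (RP) genome a backcross
individual has recovered, and how the residual donor chromatin is arranged.
The pipeline has four stages:

1. **Digital coding.** Loci where both parents are homozygous with different
   alleles are retained; everything else is discarded (a parent with a
   missing call cannot certify polymorphism). Each progeny call is coded
   1 (RP-homozygous), 2 (heterozygous with exactly the two parental
   alleles), or 0 (missing, donor-homozygous, or involving a non-parental
   allele). `PRPG = A/B x 100%` uses `A` = count of 1s and `B` = count of
   non-zero codes. A heterozygote such as A/T under parents A vs G is coded
   0, not 2: the "consistent with the parental alleles" requirement is
   enforced strictly, because an off-type allele gives no evidence of
   parental origin. An optional diagnostic (`code_zero_breakdown()`) splits
   code 0 into missing / donor-homozygous / off-type for QC, but the pipeline
   treats all three identically.
2. **Block aggregation.** SNP codes are pooled within predefined haplotype
   blocks that tile each chromosome seamlessly (BED input, 0-based
   half-open; all human-facing output is 1-based inclusive). Per block,
   `p = n_code1 / (n_code1 + n_code2)`; code-0 SNPs are excluded from both
   numerator and denominator, consistent with PRPG. A block is recovered
   (state 1) iff `p` **strictly exceeds** the threshold; ties go to the
   donor state, which is the conservative direction for breeding decisions.
   Blocks with no informative SNP are missing (state 0).
   `HTBR = NS_HTP / N_HTP` counts state-1 blocks over non-missing blocks.
3. **Smoothing.** Blocks monomorphic between the parents are assigned the
   value 1.0 (they are RP-identical by definition); blocks that are
   parentally polymorphic but all-code-0 in an individual stay missing and
   are absorbed by the surrounding segment. The per-chromosome signal of
   block proportions is segmented by circular binary segmentation (CBS) and
   each segment takes the median of its non-missing raw values as its final
   state: 1 if the median exceeds the threshold, else 2.
   `WGBR = LS_HTP / L_HTP` is the length-weighted recovered share.
4. **Fragment metrics.** Maximal state-2 segments are the unrecovered
   fragments. `CFDI = 0.5 N* + 0.5 P*`, where
   `N* = (N - N_min)/(N_max - N_min)` standardizes the fragment count within
   the analyzed cohort and `P*` is the mean over chromosomes of
   (unrecovered bp / chromosome bp). Individuals are ranked by descending
   WGBR with ascending CFDI as tie-breaker (or CFDI-first via a flag).

## Why segment on proportions, not states

CBS needs variance to work with. Segmenting the continuous block proportion
`p` (with monomorphic fill 1.0) preserves the information the median rule
needs and lets genotyping errors average out inside segments; a binarized
signal would throw away exactly the evidence that distinguishes a noisy
recovered block from a true donor block. Segmentation is per chromosome,
since recombination cannot link blocks across chromosomes.

# CBS implementation

At each recursion level the pipeline finds, exhaustively, the arc `(i, j]`
of the circularly joined segment that maximizes the absolute pooled-variance
two-sample t statistic between arc and complement. A split is accepted when
both pieces contain at least `min_width` blocks and its permutation p-value
is below `alpha`. Accepted interior arcs contribute both boundaries;
recursion continues on the resulting pieces. Afterwards an sd-undo pass
repeatedly merges the most similar adjacent pair of segments whose mean
difference is below `undo_sd` pooled within-segment standard deviations.

Numerical choices, all deterministic:

- **Tie-break:** the argmax scan keeps the first maximum in (smallest `i`,
  then smallest `j`) order.
- **Degenerate variance:** when both pieces are internally constant with
  different means the statistic is infinite and the split is accepted
  outright; a fully constant segment yields statistic 0 and no split.
- **Hybrid p-value:** when the Bonferroni bound over all admissible arcs,
  `2 * n(n+1)/2 * P(t_{n-2} > T)`, is below `alpha/1000`, the split is
  accepted without permuting — for the step-like signals this pipeline sees,
  true splits have statistics so large that the permutation p-value is
  astronomically below `alpha`, and evaluating 10,000 permutation sweeps for
  each of them would dominate the runtime without changing any decision.
  Otherwise a label-permutation test runs (Fisher-Yates shuffles from R's
  RNG, seeded per call so results are reproducible and independent of
  evaluation order), stopping early once the exceedance count makes
  `p >= alpha` inevitable. `p = (exceed + 1)/(done + 1)`.
- **Missing blocks** are dropped from the statistics but keep their
  position; at a segment boundary they attach to the following segment, and
  either way they inherit the enclosing segment's state and contribute their
  length to it.
- **All-missing segments** take the state of the nearest non-missing
  neighbor segment, left neighbor winning ties.

Defaults follow the established practice for this analysis:
`alpha = 0.001`, `undo_sd = 1.5`, `min_width = 5` blocks, `n_perm = 10000`
(so that `alpha = 0.001` is resolvable), `seed = 17`. All are exposed as
function arguments and CLI flags.

The arc scan and the permutation loop are implemented in C++ (Rcpp); an
independent brute-force R implementation of the first-split search lives in
the test suite and the two are cross-checked on a seeded battery of short
signals.

# Threshold calibration

The default block threshold is 0.5. `calibrate_threshold()` re-derives it
from data: individual-chromosomes with SNP recovery > 95% form the
recovered class, those with recovery <= 10% the unrecovered class, and the
fraction of blocks with `p` above each candidate threshold (grid 0.05-0.95,
step 0.05) is traced per class. The selected threshold is the smallest grid
point where both class curves change by less than 0.5 percentage points
over each of the next two grid steps — a concrete operationalization of the
idea that the curves have "stabilized". The extreme-class definition here
uses recovery rate alone; the spatial pattern of the discordant SNPs is not
examined. Note that where the plateau begins depends on the distribution of
SNP counts per block: with many blocks holding only a handful of SNPs the
unrecovered-class curve keeps moving through the 0.30-0.35 region (blocks
with 3-6 SNPs cross `k/n` thresholds there), so the plateau rule can settle
on a value below 0.5. The calibration report therefore always includes the
full curves and the fraction of blocks below/above 0.5 in each class, and
the pipeline keeps 0.5 as its default rather than auto-adopting the
calibrated value.

# The simulator

`simulate_population()` emulates the experimental substrate the pipeline is
designed for:

- 10 chromosomes at maize-scale physical lengths (~2.1 Gb total), genetic
  lengths defaulting to 0.7 cM/Mb (~14 crossovers per transmitted gamete);
- ~6000 seamless blocks, drawn by stick-breaking with a minimum block length
  floor, distributed over chromosomes proportionally to physical length;
- 1 + Poisson(7) polymorphic SNPs per block (mean 8, minimum 1), uniform
  positions;
- meiosis as a Poisson crossover process (count mean = genetic length in
  Morgans, uniform positions, alternating homologs, no interference);
  BC1 gametes come from the F1, BC2 populations descend from a single
  simulated BC1 parent;
- symmetric genotyping error (a wrong call becomes one of the other two
  parental-genotype states uniformly; default 2%) and missingness (default
  5%), applied to progeny only — parents are assumed to have passed
  upstream array QC. A separate helper, `flip_codes()`, models coding-level
  1<->2 error for calibration studies.

Ground truth records the donor (heterozygous) intervals, crossover
positions, and two summary fractions: `rp_fraction`, the classical
allele-weighted recurrent-parent genome proportion (heterozygous segments
count half; expectation 0.75 for BC1, 0.875 for BC2), and `rp_background`,
with heterozygous segments counted as fully non-recovered — the semantics
PRPG, HTBR and WGBR actually measure (BC1 expectation 0.5). Both are
reported because both readings are in common use and conflating them shifts
every cohort mean by a factor of two in the deviation from 1.

`truth_metrics()` rasterizes the donor intervals onto blocks. Two majority
rules are offered: `mode = "length"` (a block is truly unrecovered iff more
than half its length is donor) and `mode = "snp"` (iff at least half of its
polymorphic SNPs lie in donor intervals), the latter being the exact mirror
of the pipeline's strict `p > threshold` rule and therefore the right
reference when block-resolution agreement is being tested.

What the simulator does **not** model — and hence what passing tests do not
demonstrate about real data: crossover interference, segregation
distortion, allele-specific or clustered genotyping error, population
structure in the parents, residual heterozygosity in the RP, and block maps
whose boundaries are misspecified for the germplasm at hand.

## Known resolution limits

Two effects bound the achievable agreement with block-resolution truth even
on error-free data. First, the block containing a crossover is assigned to
a side by the CBS split statistic, which near `p = 0.5` does not always
agree with a majority rasterization of the truth. Second, `min_width = 5`
makes donor fragments spanning fewer than five blocks — including crossovers
within five blocks of a chromosome end — unresolvable; such blocks are
absorbed by the flanking segment. At maize scale (~600 blocks per
chromosome) both effects together leave per-individual WGBR within a few
hundredths of a percentage point of truth, but exact equality holds only
for individuals with no boundary ambiguity (about half a typical clean
cohort).

# Problem sizes used in the tests

The validation suite runs a full-scale clean BC1 cohort (10 chromosomes,
~6000 blocks, ~48,000 SNPs, n = 50) and the same cohort with 2% error and
5% missingness; threshold calibration uses 2000 blocks x 30 individuals
with 5% coding error; CFDI properties are exercised over 200 randomized
fragment cohorts; CBS first splits are cross-checked against brute force on
signals of up to 30 blocks. Smaller per-module fixtures are built in code.
These sizes were chosen so the whole suite, including the full-scale
cohorts, completes in about two minutes.

# Limitations

- The quality of the block map drives everything; maps built for other
  germplasm may need reconstruction, and the package validates only the
  tiling geometry, not biological block validity.
- The 0.5 threshold is robust for low-heterozygosity backcross material;
  populations with higher residual heterozygosity may need recalibration.
- CFDI is cohort-relative (`N*` uses the cohort's min/max); values are not
  comparable across cohorts, and reports should state the cohort.
- The CLI and file formats cover TSV/BED/VCF-GT inputs; imputation of
  missing genotypes and raw-array QC are out of scope, assumed upstream.
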