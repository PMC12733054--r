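Package: g2hscan
Title: Haplotype-Block Assessment of Genetic Background Recovery in Backcross Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-assisted backcross breeding that convert high-density
    SNP genotypes of backcross progeny into haplotype-block states, smooth the
    per-chromosome block signal by circular binary segmentation, and score each
    individual by SNP-level (PRPG), block-count (HTBR) and length-weighted
    whole-genome (WGBR) recurrent-parent background recovery, together with the
    Chromosomal Fragment Distribution Index (CFDI) quantifying how residual donor
    fragments are distributed across chromosomes. Includes a ground-truthed
    backcross population simulator (Poisson crossover model, genotyping error and
    missingness) for validation and parameter-recovery studies, threshold
    calibration from chromosomal extremes, recombination-breakpoint calling, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
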