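#' Identify parental polymorphic loci
#'
#' A locus is informative for background assessment only when both the
#' recurrent parent (RP) and the donor parent (DP) are non-missing, homozygous,
#' and carry different alleles. All other loci are discarded; a parent with a
#' missing call cannot certify polymorphism.
#'
#' @param loci a `g2h_loci` genotype table.
#' @param rp_sample,dp_sample column names of the recurrent and donor parent.
#' @return a `g2h_poly` data.frame with `locus_id`, `chrom`, `pos`,
#'   `rp_allele`, `dp_allele` and the attribute `locus_idx` (row indices into
#'   `loci`).
#' @export
find_polymorphic_loci <- function(loci, rp_sample, dp_sample) {
  samples <- locus_samples(loci)
  for (s in c(rp_sample, dp_sample)) {
    if (!s %in% samples) stop("unknown sample: ", s)
  }
  rp <- loci[[rp_sample]]
  dp <- loci[[dp_sample]]
  hom <- function(g) !is.na(g) & substr(g, 1L, 1L) == substr(g, 2L, 2L)
  keep <- hom(rp) & hom(dp) & rp != dp
  keep[is.na(keep)] <- FALSE
  out <- data.frame(locus_id = loci$locus_id[keep], chrom = loci$chrom[keep],
                    pos = loci$pos[keep],
                    rp_allele = substr(rp[keep], 1L, 1L),
                    dp_allele = substr(dp[keep], 1L, 1L),
                    stringsAsFactors = FALSE)
  if (!nrow(out)) {
    warning("no parental polymorphic loci found; downstream analysis is undefined")
  }
  attr(out, "locus_idx") <- which(keep)
  class(out) <- c("g2h_poly", "data.frame")
  out
}

het_call <- function(a, b) {
  ifelse(a <= b, paste0(a, b), paste0(b, a))
}

#' Digitally code one individual against the recurrent parent
#'
#' At each parental polymorphic locus: RP-homozygous calls are coded 1,
#' heterozygous calls consistent with the two parental alleles are coded 2,
#' and everything else (missing, DP-homozygous, or any call involving a
#' non-parental allele) is coded 0 and treated as missing downstream.
#'
#' @param loci a `g2h_loci` genotype table.
#' @param sample sample column name.
#' @param poly a `g2h_poly` polymorphic-locus set.
#' @return integer vector of codes in {0, 1, 2}, one per polymorphic locus.
#' @export
code_individual <- function(loci, sample, poly) {
  if (!sample %in% locus_samples(loci)) stop("unknown sample: ", sample)
  if (!nrow(poly)) stop("empty polymorphic set")
  calls <- loci[[sample]][attr(poly, "locus_idx")]
  rp_hom <- paste0(poly$rp_allele, poly$rp_allele)
  het <- het_call(poly$rp_allele, poly$dp_allele)
  code <- integer(length(calls))
  code[!is.na(calls) & calls == rp_hom] <- 1L
  code[!is.na(calls) & calls == het] <- 2L
  code
}

#' Code several individuals at once
#'
#' @param loci a `g2h_loci` genotype table.
#' @param samples character vector of sample names to code (typically every
#'   sample except the two parents).
#' @param poly a `g2h_poly` polymorphic-locus set.
#' @return integer matrix, polymorphic loci x samples, values in {0, 1, 2}.
#' @export
code_individuals <- function(loci, samples, poly) {
  m <- vapply(samples, function(s) code_individual(loci, s, poly),
              integer(nrow(poly)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(poly), dimnames = list(NULL, samples))
  m
}

#' SNP-level proportion of recurrent parent genome (PRPG)
#'
#' PRPG = A / B x 100, where A is the number of code-1 loci (homozygous
#' RP-matching) and B the number of non-zero codes (missing loci excluded).
#'
#' @param coded integer vector (or one column of a coded matrix) in {0, 1, 2}.
#' @return PRPG as a percentage in \[0, 100\].
#' @export
prpg <- function(coded) {
  b <- sum(coded != 0L)
  if (b == 0L) stop("PRPG undefined: all codes are 0 (missing)")
  100 * sum(coded == 1L) / b
}

#' Diagnostic breakdown of code-0 loci
#'
#' The pipeline treats missing calls, DP-homozygous calls and off-type calls
#' identically (code 0); this helper reports the three sources separately for
#' QC purposes.
#'
#' @inheritParams code_individual
#' @return named integer vector: `missing`, `dp_homozygous`, `off_type`.
#' @export
code_zero_breakdown <- function(loci, sample, poly) {
  calls <- loci[[sample]][attr(poly, "locus_idx")]
  rp_hom <- paste0(poly$rp_allele, poly$rp_allele)
  dp_hom <- paste0(poly$dp_allele, poly$dp_allele)
  het <- het_call(poly$rp_allele, poly$dp_allele)
  zero <- is.na(calls) | (calls != rp_hom & calls != het)
  c(missing = sum(is.na(calls)),
    dp_homozygous = sum(!is.na(calls) & calls == dp_hom),
    off_type = sum(zero & !is.na(calls) & calls != dp_hom))
}

#' Per-chromosome SNP recovery rates
#'
#' For each individual and chromosome, the fraction of non-missing coded SNPs
#' that are code 1. Used to classify chromosomal extremes for threshold
#' calibration.
#'
#' @param coded coded matrix (loci x samples) from [code_individuals()].
#' @param poly the matching `g2h_poly` set.
#' @return data.frame with `sample`, `chrom`, `recovery` (proportion, NA when
#'   a chromosome has no non-missing codes).
#' @export
chromosome_snp_recovery <- function(coded, poly) {
  chrom <- factor(poly$chrom, levels = unique(poly$chrom))
  out <- do.call(rbind, lapply(colnames(coded), function(s) {
    v <- coded[, s]
    b <- tapply(v != 0L, chrom, sum)
    a <- tapply(v == 1L, chrom, sum)
    data.frame(sample = s, chrom = levels(chrom),
               recovery = ifelse(b > 0, a / b, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
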