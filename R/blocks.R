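#' Map polymorphic loci to haplotype blocks
#'
#' @param poly a `g2h_poly` set.
#' @param blocks a `g2h_blockmap`.
#' @return integer vector: for each polymorphic locus, the row index of the
#'   containing block. Errors listing offenders if any locus falls outside
#'   every block of its chromosome.
#' @export
map_loci_to_blocks <- function(poly, blocks) {
  idx <- rep(NA_integer_, nrow(poly))
  for (c in unique(poly$chrom)) {
    li <- which(poly$chrom == c)
    bi <- which(blocks$chrom == c)
    if (!length(bi)) {
      stop("loci on chromosome absent from block map: ", c)
    }
    p0 <- poly$pos[li] - 1L  # 1-based bp -> 0-based coordinate
    k <- findInterval(p0, blocks$start[bi])
    bad <- k < 1L | p0 >= blocks$end[bi[pmax(k, 1L)]]
    if (any(bad)) {
      stop("loci outside all blocks: ",
           paste(head(poly$locus_id[li[bad]], 5L), collapse = ", "))
    }
    idx[li] <- bi[k]
  }
  idx
}

#' Blocks with no parental polymorphic locus
#'
#' These blocks are monomorphic between the parents; the smoothing stage
#' assigns them the recurrent-parent value 1.
#'
#' @inheritParams map_loci_to_blocks
#' @return integer vector of block row indices.
#' @export
monomorphic_blocks <- function(poly, blocks) {
  setdiff(seq_len(nrow(blocks)), unique(map_loci_to_blocks(poly, blocks)))
}

#' Aggregate SNP codes into per-block counts and proportions
#'
#' For every individual and block, counts the code-1 (recurrent) and code-2
#' (donor-heterozygous) SNPs; code-0 SNPs contribute to neither numerator nor
#' denominator. The recovered-SNP proportion is
#' p = n_recurrent / (n_recurrent + n_donor), undefined (NA) for blocks with
#' no informative SNP in that individual.
#'
#' @param coded coded matrix (loci x samples) from [code_individuals()].
#' @param poly the matching `g2h_poly` set.
#' @param blocks a `g2h_blockmap`.
#' @return a `g2h_track` list: `blocks` (the map), `n_recurrent`, `n_donor`,
#'   `p` (block x sample matrices), `state` (NULL until
#'   [assign_block_states()]), `monomorphic` (block indices without parental
#'   polymorphism).
#' @export
aggregate_to_blocks <- function(coded, poly, blocks) {
  if (is.null(dim(coded))) coded <- matrix(coded, ncol = 1L, dimnames = list(NULL, "ind"))
  blk <- map_loci_to_blocks(poly, blocks)
  nb <- nrow(blocks)
  samples <- colnames(coded)
  n1 <- matrix(0L, nb, length(samples), dimnames = list(blocks$block_id, samples))
  n2 <- n1
  for (s in samples) {
    v <- coded[, s]
    n1[, s] <- tabulate(blk[v == 1L], nbins = nb)
    n2[, s] <- tabulate(blk[v == 2L], nbins = nb)
  }
  tot <- n1 + n2
  p <- ifelse(tot > 0L, n1 / tot, NA_real_)
  structure(list(blocks = blocks, n_recurrent = n1, n_donor = n2, p = p,
                 state = NULL, monomorphic = setdiff(seq_len(nb), unique(blk))),
            class = "g2h_track")
}

#' Assign discrete block states from recovered-SNP proportions
#'
#' A block is recovered (state 1) iff its proportion of recurrent SNPs
#' strictly exceeds the threshold; otherwise unrecovered (state 2). Blocks
#' with no informative SNP keep state 0 (missing). The strict inequality makes
#' ties donor-leaning, which is conservative against false recovery calls.
#'
#' @param track a `g2h_track` from [aggregate_to_blocks()].
#' @param threshold recovered-SNP proportion threshold in (0, 1); default 0.5.
#' @return the track with its `state` matrix set (values in {0, 1, 2}).
#' @export
assign_block_states <- function(track, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  st <- matrix(0L, nrow(track$p), ncol(track$p), dimnames = dimnames(track$p))
  st[!is.na(track$p) & track$p > threshold] <- 1L
  st[!is.na(track$p) & track$p <= threshold] <- 2L
  track$state <- st
  track$threshold <- threshold
  track
}

#' Block-count background recovery rate (HTBR)
#'
#' HTBR = NS_HTP / N_HTP: the number of state-1 blocks over the number of
#' non-missing blocks.
#'
#' @param track a `g2h_track` with states assigned.
#' @param sample optional sample name; when omitted, a named vector for all
#'   samples is returned.
#' @return proportion(s) in \[0, 1\].
#' @export
htbr <- function(track, sample = NULL) {
  if (is.null(track$state)) stop("assign_block_states() must be called first")
  one <- function(st) {
    n <- sum(st != 0L)
    if (n == 0L) stop("HTBR undefined: all blocks missing")
    sum(st == 1L) / n
  }
  if (!is.null(sample)) return(one(track$state[, sample]))
  setNames(vapply(colnames(track$state), function(s) one(track$state[, s]),
                  numeric(1)), colnames(track$state))
}

#' Calibrate the block recovery threshold from chromosomal extremes
#'
#' Individual-chromosomes are classified as recovered (SNP recovery > 95%) or
#' unrecovered (<= 10%). The non-missing block proportions of each class are
#' pooled, and for each candidate threshold the class HTP-based recovery rate
#' (fraction of blocks with p above the threshold) is evaluated. The selected
#' threshold is the smallest grid point at which both class curves change by
#' less than `plateau_tol` over each of the next two grid steps.
#'
#' @param track a `g2h_track` from [aggregate_to_blocks()].
#' @param snp_recovery data.frame from [chromosome_snp_recovery()].
#' @param grid candidate thresholds; default 0.05 to 0.95 in steps of 0.05.
#' @param recovered_min,unrecovered_max class cutoffs on SNP recovery.
#' @param plateau_tol plateau tolerance on the rate curves (default 0.005,
#'   i.e. 0.5 percentage points).
#' @return a `g2h_calibration` list: `grid`, `rate_recovered`,
#'   `rate_unrecovered`, `selected`, `frac_below_05`/`frac_above_05` per
#'   class, class sizes.
#' @export
calibrate_threshold <- function(track, snp_recovery, grid = seq(0.05, 0.95, by = 0.05),
                                recovered_min = 0.95, unrecovered_max = 0.10,
                                plateau_tol = 0.005) {
  cls_rec <- snp_recovery[!is.na(snp_recovery$recovery) &
                            snp_recovery$recovery > recovered_min, , drop = FALSE]
  cls_unr <- snp_recovery[!is.na(snp_recovery$recovery) &
                            snp_recovery$recovery <= unrecovered_max, , drop = FALSE]
  if (!nrow(cls_rec) || !nrow(cls_unr)) {
    stop("calibration requires both extreme classes; none found for at least ",
         "one class - use the default threshold 0.5")
  }
  pool_p <- function(cls) {
    unlist(lapply(seq_len(nrow(cls)), function(i) {
      rows <- track$blocks$chrom == cls$chrom[i]
      v <- track$p[rows, cls$sample[i]]
      v[!is.na(v)]
    }), use.names = FALSE)
  }
  p_rec <- pool_p(cls_rec)
  p_unr <- pool_p(cls_unr)
  rate_rec <- vapply(grid, function(t) mean(p_rec > t), numeric(1))
  rate_unr <- vapply(grid, function(t) mean(p_unr > t), numeric(1))
  selected <- NA_real_
  for (g in seq_len(length(grid) - 2L)) {
    d_rec <- abs(diff(rate_rec[g:(g + 2L)]))
    d_unr <- abs(diff(rate_unr[g:(g + 2L)]))
    if (all(d_rec < plateau_tol) && all(d_unr < plateau_tol)) {
      selected <- grid[g]
      break
    }
  }
  if (is.na(selected)) {
    warning("no plateau found on the threshold grid; falling back to 0.5")
    selected <- 0.5
  }
  structure(list(grid = grid, rate_recovered = rate_rec,
                 rate_unrecovered = rate_unr, selected = selected,
                 frac_below_05 = c(recovered = mean(p_rec < 0.5),
                                   unrecovered = mean(p_unr < 0.5)),
                 frac_above_05 = c(recovered = mean(p_rec > 0.5),
                                   unrecovered = mean(p_unr > 0.5)),
                 n_chrom = c(recovered = nrow(cls_rec), unrecovered = nrow(cls_unr)),
                 n_blocks = c(recovered = length(p_rec), unrecovered = length(p_unr))),
            class = "g2h_calibration")
}

#' @export
print.g2h_calibration <- function(x, ...) {
  cat("Block-threshold calibration\n")
  cat(sprintf("  classes: %d recovered / %d unrecovered individual-chromosomes\n",
              x$n_chrom["recovered"], x$n_chrom["unrecovered"]))
  cat(sprintf("  blocks with p > 0.5: %.1f%% (recovered class), p < 0.5: %.1f%% (unrecovered class)\n",
              100 * x$frac_above_05["recovered"], 100 * x$frac_below_05["unrecovered"]))
  cat(sprintf("  selected threshold: %.2f\n", x$selected))
  invisible(x)
}
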