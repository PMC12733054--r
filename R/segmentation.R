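#' Build the per-block smoothing signal for one individual
#'
#' Monomorphic blocks (no parental polymorphic SNP) carry no information about
#' parental origin and are assigned the recurrent-parent value 1.0 to keep the
#' chromosome signal complete. Informative blocks carry their recovered-SNP
#' proportion p. Blocks that are polymorphic in the parents but have only
#' code-0 SNPs in this individual stay missing (NA) and are absorbed into the
#' surrounding segment at state assignment.
#'
#' @param track a `g2h_track` from [aggregate_to_blocks()].
#' @param mono_blocks block row indices without parental polymorphism;
#'   defaults to the set recorded on the track.
#' @return numeric matrix (blocks x samples) of signal values in \[0, 1\] or NA.
#' @export
fill_monomorphic <- function(track, mono_blocks = track$monomorphic) {
  sig <- track$p
  if (length(mono_blocks)) sig[mono_blocks, ] <- 1.0
  sig
}

# Naive R-level scan used as a fallback and by the first-split accessor.
best_arc <- function(x, min_width) {
  res <- cbs_best_arc_cpp(as.numeric(x), as.integer(min_width))
  if (res$i < 0) return(NULL)
  list(i = res$i, j = res$j, stat = res$stat)
}

#' First circular-binary-segmentation split of a signal
#'
#' Exhaustively maximizes the absolute pooled-variance two-sample t statistic
#' between an arc (i, j] and its complement on the circularly joined signal,
#' subject to both pieces containing at least `min_width` values. Ties break
#' toward the smallest i, then the smallest j. Returns NULL when no admissible
#' arc exists.
#'
#' @param x numeric vector without missing values.
#' @param min_width minimum piece width in blocks.
#' @return list with `i`, `j` (0-based boundaries; the arc is `x[(i+1):j]`) and
#'   `stat`, or NULL.
#' @export
cbs_first_split <- function(x, min_width = 5L) {
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in signal")
  best_arc(x, min_width)
}

# Significance of a candidate split. Deterministic hybrid evaluation:
#  - infinite statistic (two internally constant pieces, different means):
#    accepted outright;
#  - Bonferroni t-tail bound over all arc pairs far below alpha: accepted
#    without permuting;
#  - otherwise a permutation test (R RNG; caller controls the seed) with early
#    stop once p >= alpha is guaranteed.
split_significant <- function(x, stat, min_width, alpha, n_perm) {
  if (!is.finite(stat)) return(TRUE)
  if (stat <= 0) return(FALSE)
  n <- length(x)
  n_pairs <- n * (n + 1) / 2
  bound <- 2 * n_pairs * stats::pt(-stat, df = max(n - 2L, 1L))
  if (bound < alpha * 1e-3) return(TRUE)
  res <- cbs_perm_test_cpp(as.numeric(x), stat, as.integer(min_width),
                           as.integer(n_perm), alpha)
  res$p < alpha
}

# sd-undo pass: repeatedly merge the most similar adjacent pair of segments
# whose mean difference is below undo_sd pooled within-segment standard
# deviations, until stable.
undo_splits <- function(x, breaks, undo_sd) {
  repeat {
    if (!length(breaks)) return(breaks)
    bounds <- c(0L, breaks, length(x))
    k <- length(bounds) - 1L
    ratio <- rep(Inf, k - 1L)
    for (s in seq_len(k - 1L)) {
      a <- x[(bounds[s] + 1L):bounds[s + 1L]]
      b <- x[(bounds[s + 1L] + 1L):bounds[s + 2L]]
      d <- abs(mean(a) - mean(b))
      df <- length(a) + length(b) - 2L
      sp <- if (df > 0L) sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df) else 0
      ratio[s] <- if (sp > 0) d / sp else if (d > 0) Inf else 0
    }
    worst <- which.min(ratio)
    if (ratio[worst] >= undo_sd) return(breaks)
    breaks <- breaks[-worst]
  }
}

#' Circular binary segmentation of a block signal
#'
#' Recursive CBS: at each level the arc maximizing the two-sample t statistic
#' against its complement is found exhaustively; the split is accepted if its
#' permutation p-value is below `alpha` and both pieces span at least
#' `min_width` blocks (see [cbs_first_split()] and the package vignette for
#' the deterministic hybrid p-value evaluation). An accepted interior arc
#' contributes both of its boundaries. After recursion, an sd-undo pass merges
#' adjacent segments whose mean difference is below `undo_sd` pooled
#' within-segment standard deviations. Missing values are dropped from the
#' statistics but retain their position; a breakpoint reported as index b
#' separates blocks b and b+1 of the full signal.
#'
#' @param signal numeric vector of per-block values in \[0, 1\], NA allowed.
#' @param alpha significance level for the permutation test.
#' @param undo_sd sd-undo threshold.
#' @param min_width minimum piece width in blocks.
#' @param n_perm number of label permutations.
#' @param seed RNG seed used for the permutation test.
#' @return sorted integer vector of breakpoint indices (possibly empty).
#' @export
cbs_segment <- function(signal, alpha = 0.001, undo_sd = 1.5, min_width = 5L,
                        n_perm = 10000L, seed = 17L) {
  if (any(!is.finite(signal) & !is.na(signal))) stop("non-finite values in signal")
  obs <- which(!is.na(signal))
  x <- signal[obs]
  n <- length(x)
  if (n < 2L * min_width) return(integer(0))
  set.seed(seed)
  breaks <- integer(0)
  recurse <- function(lo, hi) {
    seg <- x[lo:hi]
    if (length(seg) < 2L * min_width) return()
    arc <- best_arc(seg, min_width)
    if (is.null(arc) || arc$stat <= 0) return()
    if (!split_significant(seg, arc$stat, min_width, alpha, n_perm)) return()
    i <- arc$i
    j <- arc$j
    m <- length(seg)
    if (i > 0L) breaks <<- c(breaks, lo - 1L + i)
    if (j < m) breaks <<- c(breaks, lo - 1L + j)
    cuts <- unique(c(0L, i, j, m))
    cuts <- sort(cuts[cuts >= 0L & cuts <= m])
    for (s in seq_len(length(cuts) - 1L)) {
      recurse(lo + cuts[s], lo + cuts[s + 1L] - 1L)
    }
  }
  recurse(1L, n)
  breaks <- sort(unique(breaks))
  breaks <- undo_splits(x, breaks, undo_sd)
  # map reduced-frame boundaries back to full-signal block indices
  sort(obs[breaks])
}

#' Finalize chromosome segments from breakpoints
#'
#' Segments are maximal runs of blocks between breakpoints. Each segment's
#' final state is taken from the median of its non-missing raw values:
#' state 1 (recurrent) if the median strictly exceeds the threshold, state 2
#' otherwise. Segments whose values are all missing take the state of the
#' nearest non-missing neighbor segment (left neighbor wins ties). Adjacent
#' segments with equal state are merged; genomic coordinates come from the
#' first and last block of each merged segment.
#'
#' @param signal numeric per-block signal for one chromosome.
#' @param breakpoints sorted breakpoint indices from [cbs_segment()].
#' @param blocks_chr the block-map rows of this chromosome, in order.
#' @param threshold recovered threshold on the median (default 0.5).
#' @return data.frame: `chrom`, `first_block`, `last_block` (indices within
#'   the chromosome), `start`, `end` (0-based half-open bp), `n_blocks`,
#'   `median_value`, `state`.
#' @export
finalize_segments <- function(signal, breakpoints, blocks_chr, threshold = 0.5) {
  n <- length(signal)
  stopifnot(n == nrow(blocks_chr))
  if (length(breakpoints)) {
    stopifnot(all(breakpoints >= 1L), all(breakpoints < n), !is.unsorted(breakpoints))
  }
  bounds <- c(0L, as.integer(breakpoints), n)
  k <- length(bounds) - 1L
  first <- bounds[-length(bounds)] + 1L
  last <- bounds[-1L]
  med <- numeric(k)
  state <- integer(k)
  for (s in seq_len(k)) {
    v <- signal[first[s]:last[s]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      med[s] <- NA_real_
      state[s] <- NA_integer_
    } else {
      med[s] <- stats::median(v)
      state[s] <- if (med[s] > threshold) 1L else 2L
    }
  }
  if (anyNA(state)) {
    if (all(is.na(state))) stop("all segments missing on chromosome ", blocks_chr$chrom[1])
    for (s in which(is.na(state))) {
      ok <- which(!is.na(state))
      dist <- abs(ok - s)
      pick <- ok[dist == min(dist)]
      state[s] <- state[min(pick)]  # left neighbor wins ties
    }
  }
  # merge adjacent equal-state segments
  grp <- cumsum(c(1L, diff(state) != 0L))
  out <- do.call(rbind, lapply(split(seq_len(k), grp), function(ix) {
    f <- first[ix[1L]]
    l <- last[ix[length(ix)]]
    v <- signal[f:l]
    v <- v[!is.na(v)]
    data.frame(chrom = blocks_chr$chrom[1L], first_block = f, last_block = l,
               start = blocks_chr$start[f], end = blocks_chr$end[l],
               n_blocks = l - f + 1L,
               median_value = if (length(v)) stats::median(v) else NA_real_,
               state = state[ix[1L]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call recombination-containing breakpoint intervals
#'
#' Boundaries between adjacent segments with distinct states are interpreted
#' as potential recombination sites. For each state-1/state-2 adjacency the
#' boundary between the last block of the left segment and the first block of
#' the right segment is emitted; since blocks tile the chromosome seamlessly
#' this is a single bp boundary, reported as the left block's end and the
#' right block's start in the output convention.
#'
#' @param segments finalized segment data.frame for one or more chromosomes
#'   (from [finalize_segments()], optionally row-bound).
#' @param blocks a `g2h_blockmap` (used only for column consistency checks).
#' @return data.frame: `chrom`, `left_last_block`, `right_first_block`,
#'   `left_end`, `right_start` (1-based inclusive output convention).
#' @export
call_breakpoints <- function(segments, blocks = NULL) {
  out <- list()
  for (c in unique(segments$chrom)) {
    seg <- segments[segments$chrom == c, , drop = FALSE]
    if (nrow(seg) < 2L) next
    for (s in seq_len(nrow(seg) - 1L)) {
      if (seg$state[s] != seg$state[s + 1L]) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = c,
          left_last_block = seg$last_block[s],
          right_first_block = seg$first_block[s + 1L],
          left_end = seg$end[s],            # 1-based inclusive end of left block
          right_start = seg$start[s + 1L] + 1L,  # 1-based start of right block
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), left_last_block = integer(0),
                      right_first_block = integer(0), left_end = integer(0),
                      right_start = integer(0)))
  }
  do.call(rbind, out)
}

#' Segment one individual across all chromosomes
#'
#' Convenience wrapper running [cbs_segment()] and [finalize_segments()] per
#' chromosome on a filled signal vector.
#'
#' @param signal numeric vector over all blocks (one column of
#'   [fill_monomorphic()] output).
#' @param blocks a `g2h_blockmap`.
#' @param threshold recovered threshold for segment states.
#' @inheritParams cbs_segment
#' @return data.frame of finalized segments over all chromosomes.
#' @export
segment_individual <- function(signal, blocks, threshold = 0.5, alpha = 0.001,
                               undo_sd = 1.5, min_width = 5L, n_perm = 10000L,
                               seed = 17L) {
  chroms <- unique(blocks$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    rows <- which(blocks$chrom == chroms[ci])
    sig <- signal[rows]
    bp <- cbs_segment(sig, alpha = alpha, undo_sd = undo_sd,
                      min_width = min_width, n_perm = n_perm, seed = seed)
    out[[ci]] <- finalize_segments(sig, bp, blocks[rows, , drop = FALSE],
                                   threshold = threshold)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
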