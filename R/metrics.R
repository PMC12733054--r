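#' Whole-genome background recovery rate (WGBR)
#'
#' WGBR = LS_HTP / L_HTP: the summed bp length of state-1 (recurrent)
#' segments over the total bp length of all segments.
#'
#' @param segments finalized segment data.frame for one individual (all
#'   chromosomes), with 0-based half-open `start`/`end`.
#' @return proportion in \[0, 1\].
#' @export
wgbr <- function(segments) {
  if (is.null(segments) || !nrow(segments)) stop("empty segment set")
  len <- segments$end - segments$start
  sum(len[segments$state == 1L]) / sum(len)
}

#' Extract unrecovered (donor) fragments
#'
#' Unrecovered fragments are the maximal state-2 segments, ordered by
#' (chrom, start).
#'
#' @param segments finalized segment data.frame for one individual.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open), `length`,
#'   `first_block`, `last_block`; zero rows when fully recovered.
#' @export
extract_fragments <- function(segments) {
  fr <- segments[segments$state == 2L,
                 c("chrom", "start", "end", "first_block", "last_block"),
                 drop = FALSE]
  fr$length <- fr$end - fr$start
  fr <- fr[order(match(fr$chrom, unique(segments$chrom)), fr$start), , drop = FALSE]
  rownames(fr) <- NULL
  fr[, c("chrom", "start", "end", "length", "first_block", "last_block")]
}

#' Chromosomal Fragment Distribution Index (CFDI)
#'
#' CFDI = 0.5 N* + 0.5 P*, where N* = (N - N_min) / (N_max - N_min)
#' standardizes each individual's unrecovered-fragment count N against the
#' analyzed cohort (N* = 0 for all when N_max = N_min), and P* is the mean,
#' over all chromosomes, of the unrecovered bp on that chromosome divided by
#' the chromosome length (fragment-free chromosomes contribute 0). Lower
#' values indicate fewer, more consolidated residual donor fragments.
#'
#' @param fragments_by_ind named list of fragment data.frames (one per
#'   individual, see [extract_fragments()]).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (e.g. [chrom_lengths_from_blocks()]).
#' @return data.frame: `sample`, `n_fragments`, `n_star`, `p_star`, `cfdi`.
#' @export
cfdi <- function(fragments_by_ind, chrom_lengths) {
  stopifnot(length(fragments_by_ind) >= 1L)
  samples <- names(fragments_by_ind)
  n <- vapply(fragments_by_ind, nrow, integer(1))
  n_star <- if (max(n) == min(n)) rep(0, length(n)) else (n - min(n)) / (max(n) - min(n))
  p_star <- vapply(fragments_by_ind, function(fr) {
    per_chrom <- setNames(rep(0, length(chrom_lengths)), names(chrom_lengths))
    if (nrow(fr)) {
      agg <- tapply(fr$length, fr$chrom, sum)
      per_chrom[names(agg)] <- agg
    }
    mean(per_chrom / chrom_lengths)
  }, numeric(1))
  data.frame(sample = samples, n_fragments = unname(n),
             n_star = unname(n_star), p_star = unname(p_star),
             cfdi = unname(0.5 * n_star + 0.5 * p_star),
             stringsAsFactors = FALSE)
}

#' Rank individuals for selection
#'
#' Filters to individuals with WGBR at or above `wgbr_floor`, then orders by
#' descending WGBR with ascending CFDI as tie-breaker (`by = "wgbr"`), or by
#' ascending CFDI with descending WGBR as tie-breaker (`by = "cfdi"`). The
#' dual key reflects selection for both a high background recovery rate and a
#' fragment distribution that is easy to purge in later generations.
#'
#' @param reports recovery report data.frame with `sample`, `wgbr`, `cfdi`.
#' @param wgbr_floor minimum WGBR to be considered (default 0: no filter).
#' @param by primary sort key, `"wgbr"` (default) or `"cfdi"`.
#' @return the filtered reports with a leading `rank` column.
#' @export
rank_individuals <- function(reports, wgbr_floor = 0, by = c("wgbr", "cfdi")) {
  by <- match.arg(by)
  keep <- reports[reports$wgbr >= wgbr_floor, , drop = FALSE]
  ord <- if (by == "wgbr") order(-keep$wgbr, keep$cfdi) else order(keep$cfdi, -keep$wgbr)
  keep <- keep[ord, , drop = FALSE]
  rownames(keep) <- NULL
  cbind(rank = seq_len(nrow(keep)), keep)
}

#' Diagnostic chromosome paint plot
#'
#' Draws each chromosome as a horizontal bar with recurrent segments in blue
#' and unrecovered/heterozygous segments in orange. Intended as a quick
#' graphical genotype, not a publication ideogram.
#'
#' @param segments finalized segment data.frame for one individual.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plot_chromosome_paint <- function(segments, main = "chromosome paint") {
  chroms <- unique(segments$chrom)
  nc <- length(chroms)
  max_len <- max(segments$end)
  graphics::plot(NULL, xlim = c(0, max_len), ylim = c(0.5, nc + 0.5),
                 xlab = "position (bp)", ylab = "", yaxt = "n", main = main)
  graphics::axis(2, at = rev(seq_len(nc)), labels = chroms, las = 1)
  for (ci in seq_along(chroms)) {
    seg <- segments[segments$chrom == chroms[ci], , drop = FALSE]
    y <- nc - ci + 1
    graphics::rect(seg$start, y - 0.3, seg$end, y + 0.3,
                   col = ifelse(seg$state == 1L, "#3b6fb6", "#e8a33d"),
                   border = NA)
  }
  invisible(NULL)
}
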