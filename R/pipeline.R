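stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[g2hscan] %-12s %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full background-recovery pipeline
#'
#' Executes the four workflow stages in order: (1) parental comparison and
#' digital coding, (2) block aggregation and state assignment, (3) CBS
#' smoothing with median segment states, (4) recovery metrics (PRPG, HTBR,
#' WGBR, fragments, CFDI) and ranking. Identical inputs, parameters and seed
#' produce byte-identical outputs.
#'
#' @param genotypes genotype table (`g2h_loci`) or path to a genotype TSV.
#' @param blocks block map (`g2h_blockmap`) or path to a BED4 file.
#' @param rp,dp sample names of the recurrent and donor parent.
#' @param out_dir optional output directory; when given, summary, segment,
#'   breakpoint, fragment and ranking TSVs plus a run manifest are written.
#' @param samples samples to analyze; default all except the parents.
#' @param threshold block recovery threshold (default 0.5, the calibrated
#'   optimum).
#' @param alpha,undo_sd,min_width,n_perm,seed CBS parameters (defaults 0.001,
#'   1.5, 5, 10000, 17).
#' @param wgbr_floor WGBR at or above which an individual is flagged
#'   high-recovery (default 0.95).
#' @return a `g2h_result` list: `report`, `segments` (named list per
#'   individual), `breakpoints`, `fragments` (named list), `ranking`,
#'   `track`, `poly`, `params`.
#' @export
run_pipeline <- function(genotypes, blocks, rp, dp, out_dir = NULL,
                         samples = NULL, threshold = 0.5, alpha = 0.001,
                         undo_sd = 1.5, min_width = 5L, n_perm = 10000L,
                         seed = 17L, wgbr_floor = 0.95) {
  loci <- stage("read", {
    if (is.character(genotypes)) read_genotype_matrix(genotypes) else genotypes
  })
  bmap <- if (is.character(blocks)) read_block_map(blocks) else blocks
  if (is.null(samples)) samples <- setdiff(locus_samples(loci), c(rp, dp))
  if (!length(samples)) stop("stage 'read': no progeny samples to analyze")

  coding <- stage("coding", {
    poly <- find_polymorphic_loci(loci, rp, dp)
    if (!nrow(poly)) stop("no parental polymorphic loci")
    list(poly = poly, coded = code_individuals(loci, samples, poly))
  })

  track <- stage("blocks", {
    assign_block_states(aggregate_to_blocks(coding$coded, coding$poly, bmap),
                        threshold)
  })

  seg <- stage("smoothing", {
    sig <- fill_monomorphic(track)
    out <- lapply(samples, function(s) {
      segment_individual(sig[, s], bmap, threshold = threshold, alpha = alpha,
                         undo_sd = undo_sd, min_width = min_width,
                         n_perm = n_perm, seed = seed)
    })
    names(out) <- samples
    out
  })

  res <- stage("metrics", {
    frags <- lapply(seg, extract_fragments)
    cf <- cfdi(frags, chrom_lengths_from_blocks(bmap))
    report <- data.frame(
      sample = samples,
      prpg = vapply(samples, function(s) prpg(coding$coded[, s]), numeric(1)),
      htbr = htbr(track)[samples],
      wgbr = vapply(samples, function(s) wgbr(seg[[s]]), numeric(1)),
      n_fragments = cf$n_fragments[match(samples, cf$sample)],
      cfdi = cf$cfdi[match(samples, cf$sample)],
      stringsAsFactors = FALSE)
    report$high_recovery <- report$wgbr >= wgbr_floor
    rownames(report) <- NULL
    bp <- do.call(rbind, lapply(samples, function(s) {
      b <- call_breakpoints(seg[[s]], bmap)
      if (nrow(b)) cbind(sample = s, b) else NULL
    }))
    if (is.null(bp)) {
      bp <- data.frame(sample = character(0), chrom = character(0),
                       left_last_block = integer(0), right_first_block = integer(0),
                       left_end = integer(0), right_start = integer(0))
    }
    fr_df <- do.call(rbind, lapply(samples, function(s) {
      f <- frags[[s]]
      if (nrow(f)) cbind(sample = s, f) else NULL
    }))
    list(report = report, breakpoints = bp, fragments = frags,
         fragments_df = fr_df, ranking = rank_individuals(report))
  })

  params <- list(rp = rp, dp = dp, threshold = threshold, alpha = alpha,
                 undo_sd = undo_sd, min_width = min_width, n_perm = n_perm,
                 seed = seed, wgbr_floor = wgbr_floor,
                 version = as.character(packageVersion("g2hscan")))
  out <- structure(list(report = res$report, segments = seg,
                        breakpoints = res$breakpoints, fragments = res$fragments,
                        ranking = res$ranking, track = track, poly = coding$poly,
                        params = params), class = "g2h_result")

  if (!is.null(out_dir)) {
    stage("write", {
      seg_df <- do.call(rbind, lapply(samples, function(s) cbind(sample = s, seg[[s]])))
      written <- write_reports(res$report, seg_df, out_dir,
                               breakpoints = res$breakpoints,
                               fragments = res$fragments_df,
                               ranking = res$ranking)
      manifest <- file.path(out_dir, "manifest.yaml")
      ok <- tryCatch({
        yaml::write_yaml(c(params, list(samples = samples)), manifest)
        TRUE
      }, error = function(e) {
        unlink(c(written, manifest))
        stop(conditionMessage(e))
      })
      invisible(ok)
    })
  }
  out
}

#' @export
print.g2h_result <- function(x, ...) {
  cat(sprintf("g2hscan result: %d individuals, %d chromosomes\n",
              nrow(x$report), length(unique(x$track$blocks$chrom))))
  cat(sprintf("  WGBR %.4f-%.4f (mean %.4f); %d high-recovery (>= %.0f%%)\n",
              min(x$report$wgbr), max(x$report$wgbr), mean(x$report$wgbr),
              sum(x$report$high_recovery), 100 * x$params$wgbr_floor))
  cat(sprintf("  PRPG mean %.2f%%; CFDI %.3f-%.3f\n",
              mean(x$report$prpg), min(x$report$cfdi), max(x$report$cfdi)))
  invisible(x)
}

#' Run threshold calibration end to end
#'
#' Codes the cohort, classifies chromosomal extremes by SNP recovery, and
#' calibrates the block threshold (see [calibrate_threshold()]). Optionally
#' writes the calibration curves as TSV.
#'
#' @inheritParams run_pipeline
#' @param grid candidate thresholds.
#' @return a `g2h_calibration`.
#' @export
run_calibration <- function(genotypes, blocks, rp, dp, out_dir = NULL,
                            samples = NULL, grid = seq(0.05, 0.95, by = 0.05)) {
  loci <- if (is.character(genotypes)) read_genotype_matrix(genotypes) else genotypes
  bmap <- if (is.character(blocks)) read_block_map(blocks) else blocks
  if (is.null(samples)) samples <- setdiff(locus_samples(loci), c(rp, dp))
  poly <- find_polymorphic_loci(loci, rp, dp)
  coded <- code_individuals(loci, samples, poly)
  track <- aggregate_to_blocks(coded, poly, bmap)
  cal <- calibrate_threshold(track, chromosome_snp_recovery(coded, poly), grid = grid)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tsv_fixed(data.frame(threshold = cal$grid,
                               rate_recovered = cal$rate_recovered,
                               rate_unrecovered = cal$rate_unrecovered,
                               selected = cal$grid == cal$selected),
                    file.path(out_dir, "calibration.tsv"),
                    num_cols = c("threshold", "rate_recovered", "rate_unrecovered"))
  }
  cal
}
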