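ACGT <- c("A", "C", "G", "T")

# maize-scale physical chromosome lengths (bp), largest to smallest
default_chrom_bp <- function(n_chrom) {
  if (n_chrom == 10L) {
    c(308e6, 244e6, 238e6, 247e6, 224e6, 174e6, 182e6, 181e6, 160e6, 151e6)
  } else {
    round(seq(300e6, 150e6, length.out = n_chrom))
  }
}

#' Configuration for the backcross simulator
#'
#' Defaults emulate a maize-style substrate: 10 chromosomes at physical
#' lengths near the maize genome (about 2.1 Gb total), a genome-wide average
#' recombination rate of 0.7 cM/Mb (about 14 crossovers per transmitted
#' gamete), about 6000 seamless haplotype blocks tiling the genome, and on
#' average 8 polymorphic SNPs per block (minimum 1). Genotyping error and
#' missingness rates default to 2% and 5%.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_lengths physical lengths in bp.
#' @param genetic_lengths genetic lengths in cM; default 0.7 cM per Mb.
#' @param n_blocks total number of blocks genome-wide (distributed
#'   proportionally to physical length).
#' @param snps_per_block mean SNPs per block (counts are 1 + Poisson(mean-1)).
#' @param generation backcross generation, 1 (BC1) or 2 (BC2).
#' @param n_ind population size.
#' @param error_rate symmetric genotyping-error rate applied to progeny calls.
#' @param missing_rate missing-call rate applied to progeny calls.
#' @param prop_monomorphic fraction of blocks made monomorphic between the
#'   parents (default 0: every simulated SNP is parentally polymorphic).
#' @param seed RNG seed; the whole simulation is deterministic given the seed.
#' @return a `g2h_sim_config` list.
#' @export
sim_config <- function(n_chrom = 10L, chrom_lengths = NULL, genetic_lengths = NULL,
                       n_blocks = 6000L, snps_per_block = 8, generation = 1L,
                       n_ind = 50L, error_rate = 0.02, missing_rate = 0.05,
                       prop_monomorphic = 0, seed = 1L) {
  if (is.null(chrom_lengths)) chrom_lengths <- default_chrom_bp(n_chrom)
  stopifnot(length(chrom_lengths) == n_chrom, all(chrom_lengths > 0))
  if (is.null(genetic_lengths)) genetic_lengths <- chrom_lengths / 1e6 * 0.7
  stopifnot(length(genetic_lengths) == n_chrom, all(genetic_lengths > 0))
  for (r in c(error_rate, missing_rate, prop_monomorphic)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (!generation %in% c(1L, 2L)) stop("generation must be 1 or 2")
  if (n_ind < 1L) stop("population size must be >= 1")
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_lengths = as.numeric(chrom_lengths),
                 genetic_lengths = as.numeric(genetic_lengths),
                 n_blocks = as.integer(n_blocks),
                 snps_per_block = snps_per_block,
                 generation = as.integer(generation), n_ind = as.integer(n_ind),
                 error_rate = error_rate, missing_rate = missing_rate,
                 prop_monomorphic = prop_monomorphic, seed = as.integer(seed)),
            class = "g2h_sim_config")
}

# seamless block boundaries for one chromosome: stick-breaking with a minimum
# block-length floor; returns 0-based half-open start/end vectors
sim_block_bounds <- function(len, nb) {
  if (nb == 1L) return(list(start = 0, end = len))
  min_len <- max(1, floor(len / nb / 4))
  w <- rgamma(nb, shape = 3)
  extra <- len - nb * min_len
  ex <- floor(extra * w / sum(w))
  rem <- extra - sum(ex)
  if (rem > 0) ex[seq_len(rem)] <- ex[seq_len(rem)] + 1
  sizes <- min_len + ex
  end <- cumsum(sizes)
  list(start = c(0, end[-nb]), end = end)
}

# intersect two sets of disjoint sorted intervals (matrices with columns
# start, end; 0-based half-open)
intersect_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(0), 0, 2))
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1])
    e <- pmin(a[i, 2], b[, 2])
    keep <- e > s
    if (any(keep)) out[[length(out) + 1L]] <- cbind(s[keep], e[keep])
  }
  if (!length(out)) return(matrix(numeric(0), 0, 2))
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

# One meiosis from an individual carrying a pure-RP homolog and a mosaic
# homolog whose donor (DP) intervals are given. Crossover counts are Poisson
# with mean = genetic length in Morgans, positions uniform in bp (no
# interference). Returns the gamete's donor intervals and crossover positions.
sim_gamete <- function(mosaic_donor, chrom_lengths, genetic_morgans) {
  nc <- length(chrom_lengths)
  donor <- vector("list", nc)
  xo <- vector("list", nc)
  for (c in seq_len(nc)) {
    L <- chrom_lengths[c]
    k <- rpois(1L, genetic_morgans[c])
    pos <- sort(runif(k, 0, L))
    xo[[c]] <- pos
    bounds <- c(0, pos, L)
    first <- sample(c(TRUE, FALSE), 1L)  # TRUE: start on the mosaic homolog
    take_mosaic <- rep(c(first, !first), length.out = length(bounds) - 1L)
    if (any(take_mosaic)) {
      chosen <- cbind(bounds[-length(bounds)][take_mosaic], bounds[-1L][take_mosaic])
      donor[[c]] <- intersect_intervals(chosen, mosaic_donor[[c]])
    } else {
      donor[[c]] <- matrix(numeric(0), 0, 2)
    }
  }
  list(donor = donor, crossovers = xo)
}

#' Simulate a ground-truthed backcross population
#'
#' Generates a seamless block map, SNP positions within blocks, fully
#' homozygous parents with distinct alleles at every polymorphic SNP, and
#' backcross progeny whose gametes follow a Poisson crossover model (mean =
#' genetic length in Morgans, uniform positions, no interference). BC1
#' progeny are formed from F1 gametes; for BC2 a single BC1 parent is drawn
#' first and the population descends from it. Progeny are either
#' RP-homozygous or heterozygous at each locus; donor homozygosity can arise
#' only from injected genotyping error. Error and missingness are applied to
#' progeny calls only (parents are assumed to have passed upstream array QC).
#'
#' @param config a `g2h_sim_config`.
#' @param make_genotypes build the genotype call table (set FALSE for fast
#'   truth-only simulations).
#' @return a `g2h_sim` list: `loci` (genotype table; NULL when
#'   `make_genotypes = FALSE`), `blocks`, `chrom_table` (with genetic
#'   lengths), `truth` (donor intervals per individual, 0-based half-open;
#'   `rp_fraction`, the classical allele-weighted recurrent-parent genome
#'   fraction where heterozygous segments count half, expectation 0.75 for
#'   BC1 and 0.875 for BC2; `rp_background`, the fraction with heterozygous
#'   segments counted as non-recovered, the semantics shared by PRPG, HTBR
#'   and WGBR; crossover positions of the final meiosis), `alleles`
#'   (per-SNP RP/DP alleles), `samples`, `rp_sample`, `dp_sample`, `config`.
#' @export
simulate_population <- function(config, make_genotypes = TRUE) {
  stopifnot(inherits(config, "g2h_sim_config"))
  set.seed(config$seed)
  nc <- config$n_chrom
  chroms <- paste0("chr", seq_len(nc))
  lens <- config$chrom_lengths

  # block map: counts proportional to physical length (largest remainder)
  raw <- config$n_blocks * lens / sum(lens)
  nb <- floor(raw)
  short <- config$n_blocks - sum(nb)
  if (short > 0) {
    nb[order(raw - floor(raw), decreasing = TRUE)[seq_len(short)]] <-
      nb[order(raw - floor(raw), decreasing = TRUE)[seq_len(short)]] + 1L
  }
  nb <- pmax(nb, 1L)
  bm <- do.call(rbind, lapply(seq_len(nc), function(c) {
    b <- sim_block_bounds(lens[c], nb[c])
    data.frame(block_id = sprintf("%s_b%04d", chroms[c], seq_len(nb[c])),
               chrom = chroms[c], start = b$start, end = b$end,
               stringsAsFactors = FALSE)
  }))
  blocks <- as_block_map(bm)

  # SNPs: 1 + Poisson(mean - 1) per block, uniform unique positions
  cnt <- 1L + rpois(nrow(blocks), max(config$snps_per_block - 1, 0))
  cnt <- pmin(cnt, blocks$end - blocks$start)
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    blocks$start[i] + sort(sample.int(blocks$end[i] - blocks$start[i], cnt[i]))
  }))  # 1-based positions inside (start, end]
  snp_chrom <- rep(blocks$chrom, cnt)
  n_snp <- length(pos)

  rp_al <- sample(ACGT, n_snp, replace = TRUE)
  dp_al <- ACGT[(match(rp_al, ACGT) - 1L + sample.int(3L, n_snp, replace = TRUE)) %% 4L + 1L]
  if (config$prop_monomorphic > 0) {
    mono <- sample.int(nrow(blocks), round(config$prop_monomorphic * nrow(blocks)))
    dp_al[rep(seq_len(nrow(blocks)) %in% mono, cnt)] <- rp_al[rep(seq_len(nrow(blocks)) %in% mono, cnt)]
  }

  # pedigree: meiosis chain down to the requested generation
  morgans <- config$genetic_lengths / 100
  full_donor <- lapply(lens, function(L) matrix(c(0, L), 1, 2))
  parent_donor <- full_donor  # F1's mosaic homolog is pure DP
  parent_donor_len <- sum(lens)
  if (config$generation == 2L) {
    bc1 <- sim_gamete(full_donor, lens, morgans)
    parent_donor <- bc1$donor
    parent_donor_len <- sum(vapply(parent_donor, function(m) {
      if (nrow(m)) sum(m[, 2] - m[, 1]) else 0
    }, numeric(1)))
  }
  samples <- sprintf("BC%d_%03d", config$generation, seq_len(config$n_ind))
  donor_list <- vector("list", config$n_ind)
  xo_list <- vector("list", config$n_ind)
  for (i in seq_len(config$n_ind)) {
    g <- sim_gamete(parent_donor, lens, morgans)
    donor_list[[i]] <- g$donor
    xo_list[[i]] <- g$crossovers
  }
  names(donor_list) <- names(xo_list) <- samples

  genome_len <- sum(lens)
  donor_df <- do.call(rbind, lapply(samples, function(s) {
    d <- donor_list[[s]]
    rows <- lapply(seq_len(nc), function(c) {
      if (!nrow(d[[c]])) return(NULL)
      data.frame(sample = s, chrom = chroms[c], start = d[[c]][, 1],
                 end = d[[c]][, 2], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (is.null(donor_df)) {
    donor_df <- data.frame(sample = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0))
  }
  donor_len <- vapply(samples, function(s) {
    d <- donor_df[donor_df$sample == s, , drop = FALSE]
    sum(d$end - d$start)
  }, numeric(1))
  # allele-weighted recurrent-parent genome fraction (heterozygous donor
  # segments count half): the classical backcross expectation, 0.75 for BC1
  rp_fraction <- 1 - donor_len / (2 * genome_len)
  # background fraction with heterozygous segments counted as non-recovered,
  # matching the code-2 semantics of PRPG/HTBR/WGBR: 0.5 expected for BC1
  rp_background <- 1 - donor_len / genome_len
  xo_df <- do.call(rbind, lapply(samples, function(s) {
    rows <- lapply(seq_len(nc), function(c) {
      p <- xo_list[[s]][[c]]
      if (!length(p)) return(NULL)
      data.frame(sample = s, chrom = chroms[c], pos = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (is.null(xo_df)) {
    xo_df <- data.frame(sample = character(0), chrom = character(0), pos = numeric(0))
  }

  loci <- NULL
  if (make_genotypes) {
    rp_hom <- paste0(rp_al, rp_al)
    dp_hom <- paste0(dp_al, dp_al)
    het <- het_call(rp_al, dp_al)
    het[dp_al == rp_al] <- rp_hom[dp_al == rp_al]
    df <- data.frame(locus_id = sprintf("S%06d", seq_len(n_snp)),
                     chrom = snp_chrom, pos = as.integer(pos),
                     RP = rp_hom, DP = dp_hom, stringsAsFactors = FALSE)
    for (s in samples) {
      is_het <- logical(n_snp)
      d <- donor_list[[s]]
      for (c in seq_len(nc)) {
        if (!nrow(d[[c]])) next
        ix <- which(snp_chrom == chroms[c])
        p0 <- pos[ix] - 1L  # SNP bp -> 0-based coordinate
        k <- findInterval(p0, d[[c]][, 1])
        is_het[ix[k >= 1L & p0 < d[[c]][pmax(k, 1L), 2]]] <- TRUE
      }
      calls <- ifelse(is_het, het, rp_hom)
      calls <- inject_noise(calls, rp_hom, dp_hom, het,
                            config$error_rate, config$missing_rate)
      df[[s]] <- calls
    }
    loci <- as_locus_table(df)
  }

  structure(list(
    loci = loci, blocks = blocks,
    chrom_table = data.frame(chrom = chroms, length = lens,
                             genetic_length = config$genetic_lengths,
                             stringsAsFactors = FALSE),
    truth = list(donor = donor_df, rp_fraction = rp_fraction,
                 rp_background = rp_background, crossovers = xo_df,
                 parent_donor_len = parent_donor_len),
    alleles = data.frame(locus_id = sprintf("S%06d", seq_len(n_snp)),
                         chrom = snp_chrom, pos = as.integer(pos),
                         rp_allele = rp_al, dp_allele = dp_al,
                         stringsAsFactors = FALSE),
    samples = samples, rp_sample = "RP", dp_sample = "DP",
    config = config), class = "g2h_sim")
}

# symmetric genotype error: an erroneous call is replaced by one of the other
# two parental-genotype states uniformly; missingness masks calls
inject_noise <- function(calls, rp_hom, dp_hom, het, error_rate, missing_rate) {
  n <- length(calls)
  if (error_rate > 0) {
    err <- which(runif(n) < error_rate)
    if (length(err)) {
      states <- cbind(rp_hom[err], het[err], dp_hom[err])
      cur <- calls[err]
      pick <- vapply(seq_along(err), function(k) {
        alt <- setdiff(states[k, ], cur[k])
        if (!length(alt)) cur[k] else alt[sample.int(length(alt), 1L)]
      }, "")
      calls[err] <- pick
    }
  }
  if (missing_rate > 0) {
    calls[runif(n) < missing_rate] <- NA_character_
  }
  calls
}

#' Add genotyping noise to a clean simulated population
#'
#' Re-applies the simulator's error and missingness model to the progeny
#' calls of an existing (typically error-free) simulation, leaving parents
#' and the ground truth untouched. Useful for comparing clean and noisy
#' analyses of the same cohort.
#'
#' @param sim a `g2h_sim` with genotypes.
#' @param error_rate,missing_rate noise rates.
#' @param seed RNG seed for the noise draw.
#' @return the `g2h_sim` with noisy progeny calls.
#' @export
add_genotype_noise <- function(sim, error_rate, missing_rate, seed = 1L) {
  stopifnot(inherits(sim, "g2h_sim"), !is.null(sim$loci))
  set.seed(seed)
  al <- sim$alleles[match(sim$loci$locus_id, sim$alleles$locus_id), ]
  rp_hom <- paste0(al$rp_allele, al$rp_allele)
  dp_hom <- paste0(al$dp_allele, al$dp_allele)
  het <- het_call(al$rp_allele, al$dp_allele)
  het[al$dp_allele == al$rp_allele] <- rp_hom[al$dp_allele == al$rp_allele]
  for (s in sim$samples) {
    sim$loci[[s]] <- inject_noise(sim$loci[[s]], rp_hom, dp_hom, het,
                                  error_rate, missing_rate)
  }
  sim
}

#' Symmetric code-flip noise
#'
#' Flips digital codes 1 <-> 2 with the given probability (code 0 untouched).
#' Models SNP-coding error directly at the code level, e.g. for threshold
#' calibration studies.
#'
#' @param coded coded matrix or vector in {0, 1, 2}.
#' @param rate flip probability per non-zero code.
#' @return the flipped codes (same shape).
#' @export
flip_codes <- function(coded, rate) {
  nz <- which(coded != 0L)
  fl <- nz[runif(length(nz)) < rate]
  coded[fl] <- 3L - coded[fl]
  coded
}

#' Block-resolution ground truth
#'
#' Rasterizes the true donor segments of each simulated individual onto the
#' block map and reports the truth at the pipeline's resolution. With
#' `mode = "length"` a block is truly unrecovered iff more than half of its
#' length is donor-overlapped; with `mode = "snp"` (requires `poly`) iff at
#' least half of its parental polymorphic SNPs lie in donor intervals, the
#' exact mirror of the pipeline's strict `p > threshold` state rule.
#'
#' @param sim a `g2h_sim` (or a truth list with `donor` and `rp_fraction`).
#' @param blocks a `g2h_blockmap`.
#' @param mode `"length"` (default) or `"snp"`.
#' @param poly a `g2h_poly` set, required for `mode = "snp"`.
#' @return data.frame with `sample`, `true_wgbr` (block-resolution), and
#'   `n_fragments`; the logical blocks x samples unrecovered matrix is
#'   attached as attribute `"unrecovered"`.
#' @export
truth_metrics <- function(sim, blocks, mode = c("length", "snp"), poly = NULL) {
  mode <- match.arg(mode)
  truth <- if (inherits(sim, "g2h_sim")) sim$truth else sim
  samples <- unique(c(truth$donor$sample, names(truth$rp_fraction)))
  nb <- nrow(blocks)
  blen <- blocks$end - blocks$start
  unrec <- matrix(FALSE, nb, length(samples), dimnames = list(blocks$block_id, samples))
  if (mode == "snp") {
    if (is.null(poly)) stop("mode = 'snp' requires the polymorphic set")
    blk <- map_loci_to_blocks(poly, blocks)
    tot_snp <- tabulate(blk, nbins = nb)
  }
  for (s in samples) {
    d <- truth$donor[truth$donor$sample == s, , drop = FALSE]
    if (!nrow(d)) next
    if (mode == "length") {
      ov <- numeric(nb)
      for (i in seq_len(nrow(d))) {
        rows <- which(blocks$chrom == d$chrom[i])
        o <- pmin(blocks$end[rows], d$end[i]) - pmax(blocks$start[rows], d$start[i])
        pos <- o > 0
        ov[rows[pos]] <- ov[rows[pos]] + o[pos]
      }
      unrec[, s] <- ov > 0.5 * blen
    } else {
      in_donor <- logical(nrow(poly))
      for (i in seq_len(nrow(d))) {
        hit <- poly$chrom == d$chrom[i] & (poly$pos - 1L) >= d$start[i] &
          (poly$pos - 1L) < d$end[i]
        in_donor[hit] <- TRUE
      }
      dn <- tabulate(blk[in_donor], nbins = nb)
      unrec[, s] <- tot_snp > 0L & dn >= 0.5 * tot_snp
    }
  }
  res <- data.frame(sample = samples,
                    true_wgbr = vapply(samples, function(s) {
                      1 - sum(blen[unrec[, s]]) / sum(blen)
                    }, numeric(1)),
                    n_fragments = vapply(samples, function(s) {
                      u <- unrec[, s]
                      sum(vapply(split(u, factor(blocks$chrom, levels = unique(blocks$chrom))),
                                 function(v) sum(diff(c(FALSE, v)) == 1L), numeric(1)))
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "unrecovered") <- unrec
  res
}

#' Fraction of true crossovers localized by called breakpoints
#'
#' For each true crossover of the final meiosis, checks whether a called
#' segment boundary lies within `tol_blocks` blocks of the block containing
#' the crossover, on the same chromosome of the same individual.
#'
#' @param sim a `g2h_sim`.
#' @param segments_by_ind named list of finalized segment data.frames.
#' @param blocks a `g2h_blockmap`.
#' @param tol_blocks localization tolerance in blocks (default 2).
#' @return list with `rate` (fraction localized), `n_crossovers`, and the
#'   per-crossover logical vector `localized`.
#' @export
localize_crossovers <- function(sim, segments_by_ind, blocks, tol_blocks = 2L) {
  xo <- sim$truth$crossovers
  xo <- xo[xo$sample %in% names(segments_by_ind), , drop = FALSE]
  loc <- logical(nrow(xo))
  for (r in seq_len(nrow(xo))) {
    rows <- which(blocks$chrom == xo$chrom[r])
    bx <- findInterval(xo$pos[r], blocks$start[rows])  # block index within chrom
    seg <- segments_by_ind[[xo$sample[r]]]
    seg <- seg[seg$chrom == xo$chrom[r], , drop = FALSE]
    if (nrow(seg) < 2L) next
    bnd <- seg$last_block[-nrow(seg)]  # boundary after this block index
    loc[r] <- any(pmin(abs(bx - bnd), abs(bx - (bnd + 1L))) <= tol_blocks)
  }
  list(rate = if (nrow(xo)) mean(loc) else NA_real_, n_crossovers = nrow(xo),
       localized = loc)
}
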