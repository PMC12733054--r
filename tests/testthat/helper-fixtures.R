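# in-code fixture builders and independent oracles used across test files

# tiny locus table: calls is a named list of per-sample call vectors
make_loci <- function(chrom, pos, calls, locus_id = sprintf("L%02d", seq_along(pos))) {
  df <- data.frame(locus_id = locus_id, chrom = chrom, pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  for (s in names(calls)) df[[s]] <- normalize_calls(calls[[s]])
  as_locus_table(df)
}

make_blocks <- function(chrom, start, end,
                        block_id = sprintf("B%02d", seq_along(start))) {
  as_block_map(data.frame(block_id = block_id, chrom = chrom,
                          start = as.integer(start), end = as.integer(end),
                          stringsAsFactors = FALSE))
}

write_genotype_fixture <- function(loci, path = tempfile(fileext = ".tsv")) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NN")
  path
}

write_bed_fixture <- function(blocks, path = tempfile(fileext = ".bed")) {
  write.table(blocks[, c("chrom", "start", "end", "block_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  path
}

# independent brute-force oracle for the first CBS split: plain double loop,
# statistics computed from scratch with mean()/sum() (no cumulative sums)
oracle_first_split <- function(x, min_width) {
  n <- length(x)
  best <- -1
  bi <- bj <- NA_integer_
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      if (i == 0 && j == n) next
      n1 <- j - i
      n2 <- n - n1
      if (n1 < min_width || n2 < min_width) next
      arc <- x[(i + 1):j]
      comp <- x[setdiff(seq_len(n), (i + 1):j)]
      d <- abs(mean(arc) - mean(comp))
      sp2 <- (sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)) / (n - 2)
      denom <- sp2 * (1 / n1 + 1 / n2)
      t <- if (denom < 1e-30) (if (d > 1e-12) Inf else 0) else d / sqrt(denom)
      if (t > best) {
        best <- t
        bi <- i
        bj <- j
      }
    }
  }
  if (best < 0) return(NULL)
  list(i = bi, j = bj, stat = best)
}

# independent per-bp rasterization oracle (small chromosomes only): a block is
# unrecovered iff more than half of its base pairs lie inside donor intervals
oracle_rasterize <- function(donor_df, blocks, sample) {
  unrec <- logical(nrow(blocks))
  d <- donor_df[donor_df$sample == sample, , drop = FALSE]
  for (b in seq_len(nrow(blocks))) {
    bp <- seq(blocks$start[b], blocks$end[b] - 1L)  # 0-based positions
    inside <- rep(FALSE, length(bp))
    dd <- d[d$chrom == blocks$chrom[b], , drop = FALSE]
    for (r in seq_len(nrow(dd))) {
      inside <- inside | (bp >= dd$start[r] & bp < dd$end[r])
    }
    unrec[b] <- sum(inside) > length(bp) / 2
  }
  unrec
}

# four-individual toy cohort used by io/metrics tests: two chromosomes with
# hand-placed donor blocks
toy_pipeline_input <- function() {
  blocks <- make_blocks(rep(c("chr1", "chr2"), each = 4),
                        rep(c(0, 100, 250, 400), 2),
                        rep(c(100, 250, 400, 500), 2),
                        block_id = sprintf("B%02d", 1:8))
  pos <- c(10, 50, 120, 200, 300, 380, 410, 480,
           10, 50, 120, 200, 300, 380, 410, 480)
  chrom <- rep(c("chr1", "chr2"), each = 8)
  rp <- rep("AA", 16)
  dp <- rep("GG", 16)
  ind1 <- rep("AA", 16)                      # fully recovered
  ind2 <- c(rep("AG", 8), rep("AA", 8))      # chr1 donor het
  list(loci = make_loci(chrom, pos, list(RP = rp, DP = dp, I1 = ind1, I2 = ind2)),
       blocks = blocks)
}
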