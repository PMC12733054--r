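seg_row <- function(chrom, start, end, state, first = 1L, last = 1L) {
  data.frame(chrom = chrom, first_block = first, last_block = last,
             start = start, end = end, n_blocks = last - first + 1L,
             median_value = ifelse(state == 1L, 1, 0), state = state,
             stringsAsFactors = FALSE)
}

test_that("wgbr is the length-weighted state-1 share", {
  seg <- rbind(seg_row("chr1", 0, 3e6, 1L), seg_row("chr1", 3e6, 4e6, 2L))
  expect_equal(wgbr(seg), 0.75)
  expect_equal(wgbr(seg_row("chr1", 0, 1e6, 1L)), 1)
  expect_error(wgbr(seg[0, ]), "empty")
  # equals the block-length-weighted mean of (state == 1)
  blocks <- make_blocks("chr1", c(0, 50, 150, 300), c(50, 150, 300, 500))
  sig <- c(1, 1, 0, 0)
  segs <- finalize_segments(sig, 2L, blocks, threshold = 0.5)
  len <- blocks$end - blocks$start
  expect_equal(wgbr(segs), sum(len * c(1, 1, 0, 0)) / sum(len))
})

test_that("fragment extraction returns ordered maximal state-2 segments", {
  seg <- rbind(seg_row("chr1", 0, 10, 1L), seg_row("chr1", 10, 25, 2L),
               seg_row("chr1", 25, 60, 1L), seg_row("chr1", 60, 100, 2L),
               seg_row("chr2", 0, 100, 1L))
  fr <- extract_fragments(seg)
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$length, c(15, 40))
  # conservation: fragment lengths sum to total x (1 - WGBR)
  expect_equal(sum(fr$length), sum(seg$end - seg$start) * (1 - wgbr(seg)))
  expect_equal(nrow(extract_fragments(seg_row("chr1", 0, 10, 1L))), 0L)
})

test_that("cfdi combines standardized fragment count and mean chromosome load", {
  chrom_len <- c(chr1 = 100, chr2 = 100)
  frag <- function(n, len, chrom = "chr1") {
    if (n == 0) {
      return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                        length = numeric(0)))
    }
    data.frame(chrom = chrom, start = seq_len(n) * 2, end = seq_len(n) * 2 + len,
               length = rep(len, n))
  }
  # zero fragments and cohort-minimum count: CFDI = 0
  res <- cfdi(list(a = frag(0, 0), b = frag(2, 10)), chrom_len)
  expect_equal(res$cfdi[res$sample == "a"], 0)
  # cohort built so one individual has N* = 0.2 and P* = 0.1 -> CFDI = 0.15
  res15 <- cfdi(list(a = frag(0, 0), b = frag(5, 1), c = frag(1, 20)), chrom_len)
  expect_equal(res15$n_star[res15$sample == "c"], 0.2)
  expect_equal(res15$p_star[res15$sample == "c"], 0.1)
  expect_equal(res15$cfdi[res15$sample == "c"], 0.15)
  # equal unrecovered length: consolidated fragments score strictly lower
  res2 <- cfdi(list(scattered = frag(10, 2), consolidated = frag(2, 10)), chrom_len)
  expect_lt(res2$cfdi[res2$sample == "consolidated"],
            res2$cfdi[res2$sample == "scattered"])
  expect_equal(res2$p_star[1], res2$p_star[2])
  # degenerate cohort: N* = 0 for all
  res3 <- cfdi(list(a = frag(3, 4), b = frag(3, 6)), chrom_len)
  expect_equal(res3$n_star, c(0, 0))
})

test_that("ranking prefers high WGBR then low CFDI, with a CFDI-first option", {
  rep_df <- data.frame(sample = c("A", "B", "C"),
                       wgbr = c(0.97, 0.97, 0.99),
                       cfdi = c(0.24, 0.12, 0.30), stringsAsFactors = FALSE)
  rk <- rank_individuals(rep_df)
  expect_equal(rk$sample, c("C", "B", "A"))  # equal WGBR: lower CFDI first
  rk2 <- rank_individuals(rep_df, by = "cfdi")
  expect_equal(rk2$sample, c("B", "A", "C"))
  rk3 <- rank_individuals(rep_df, wgbr_floor = 0.98)
  expect_equal(rk3$sample, "C")
  expect_equal(nrow(rank_individuals(rep_df[1, ])), 1L)
})
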