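#' @useDynLib g2hscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rpois runif rgamma cor setNames
#' @importFrom utils read.delim write.table packageVersion head
NULL

MISSING_CALL <- NA_character_

#' Normalize diploid allele calls to unordered pairs
#'
#' Calls are strings of two bases over A/C/G/T ("AG", "GA", ...). Phase is
#' never used, so "GA" and "AG" denote the same genotype and are normalized to
#' the alphabetically sorted form. Anything not matching two valid bases, or
#' listed in `missing_codes`, becomes the missing sentinel (`NA`).
#'
#' @param calls character vector of raw calls.
#' @param missing_codes character vector of strings to treat as missing.
#' @return character vector of normalized calls with `NA` for missing.
#' @export
normalize_calls <- function(calls, missing_codes = c("NN", "--", ".", "")) {
  calls <- as.character(calls)
  calls[calls %in% missing_codes | is.na(calls)] <- NA_character_
  ok <- !is.na(calls)
  if (any(ok)) {
    valid <- grepl("^[ACGT]{2}$", calls[ok])
    idx <- which(ok)
    calls[idx[!valid]] <- NA_character_
    idx <- idx[valid]
    if (length(idx)) {
      a1 <- substr(calls[idx], 1L, 1L)
      a2 <- substr(calls[idx], 2L, 2L)
      swap <- a1 > a2
      calls[idx][swap] <- paste0(a2[swap], a1[swap])
    }
  }
  calls
}

#' Read a genotype matrix from tab-separated text
#'
#' Expects a header row with columns `locus_id`, `chrom`, `pos` followed by one
#' column per sample holding diploid calls (e.g. "AA", "AG"). Calls are
#' normalized to unordered pairs; unrecognized strings map to missing. Loci are
#' returned sorted by (chrom, pos), with chromosomes ordered by first
#' appearance in the file.
#'
#' @param path path to the TSV file.
#' @param missing_codes call strings treated as missing.
#' @return a `g2h_loci` data.frame: `locus_id`, `chrom`, `pos`, then one
#'   character column per sample.
#' @export
read_genotype_matrix <- function(path, missing_codes = c("NN", "--", ".", "")) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  need <- c("locus_id", "chrom", "pos")
  if (!all(need %in% names(df)[seq_len(3)])) {
    stop("genotype matrix must start with columns locus_id, chrom, pos")
  }
  samples <- names(df)[-seq_len(3)]
  if (anyDuplicated(samples)) {
    stop("duplicate sample names in genotype matrix: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) stop("non-integer pos values in genotype matrix")
  for (s in samples) df[[s]] <- normalize_calls(df[[s]], missing_codes)
  df$pos <- pos
  as_locus_table(df)
}

#' Construct/validate a locus table
#'
#' @param df data.frame with `locus_id`, `chrom`, `pos` and sample columns.
#' @return the validated, (chrom, pos)-sorted `g2h_loci` data.frame.
#' @export
as_locus_table <- function(df) {
  if (any(df$pos < 1L)) stop("pos must be >= 1")
  key <- paste(df$chrom, df$pos, df$locus_id)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, locus_id) rows")
  chrom_levels <- unique(df$chrom)
  ord <- order(match(df$chrom, chrom_levels), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("g2h_loci", "data.frame")
  df
}

#' Sample names of a locus table
#' @param loci a `g2h_loci` data.frame.
#' @return character vector of sample column names.
#' @export
locus_samples <- function(loci) setdiff(names(loci), c("locus_id", "chrom", "pos"))

#' Read a genotype matrix from a VCF file
#'
#' Convenience reader producing the same locus table as
#' [read_genotype_matrix()]. Only the GT field of biallelic SNP records is
#' used; phase separators are ignored. Requires the `vcfR` package.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return a `g2h_loci` data.frame.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotype_vcf requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  ref <- ref[keep]
  alt <- alt[keep]
  call_of <- function(g, i) {
    if (is.na(g)) return(NA_character_)
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_character_)
    b <- ifelse(al == "0", ref[i], ifelse(al == "1", alt[i], NA))
    if (anyNA(b)) return(NA_character_)
    paste(sort(b), collapse = "")
  }
  calls <- matrix(NA_character_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) {
    calls[, j] <- vapply(seq_len(nrow(gt)), function(i) call_of(gt[i, j], i), "")
  }
  id <- fix[keep, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[is.na(id) | id == "."]
  df <- data.frame(locus_id = id, chrom = fix[keep, "CHROM"],
                   pos = as.integer(fix[keep, "POS"]), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(calls))) df[[colnames(calls)[j]]] <- unname(calls[, j])
  as_locus_table(df)
}

#' Read a haplotype-block map from BED4
#'
#' Input is standard BED (0-based, half-open) with columns chrom, start, end,
#' block_id. Within each chromosome blocks must tile the sequence seamlessly:
#' ordered, non-overlapping, gap-free. Coordinates are kept 0-based half-open
#' internally; human-facing outputs are 1-based inclusive.
#'
#' @param path path to the BED file.
#' @param chrom_table optional chromosome table (see [read_chrom_table()]);
#'   when given, the blocks of each chromosome must cover exactly its length.
#' @return a `g2h_blockmap` data.frame: `block_id`, `chrom`, `start`, `end`.
#' @export
read_block_map <- function(path, chrom_table = NULL) {
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = c("character", "numeric", "numeric", "character"))
  names(df) <- c("chrom", "start", "end", "block_id")
  as_block_map(df[, c("block_id", "chrom", "start", "end")], chrom_table)
}

#' Construct/validate a block map
#'
#' @param df data.frame with `block_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_table optional chromosome table for total-length validation.
#' @return a validated `g2h_blockmap` data.frame, blocks ordered per
#'   chromosome (chromosomes by first appearance).
#' @export
as_block_map <- function(df, chrom_table = NULL) {
  chrom_levels <- unique(df$chrom)
  df <- df[order(match(df$chrom, chrom_levels), df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end <= df$start)) stop("block end must exceed start")
  for (c in chrom_levels) {
    b <- df[df$chrom == c, , drop = FALSE]
    if (nrow(b) > 1L) {
      gap <- which(b$start[-1L] != b$end[-nrow(b)])
      if (length(gap)) {
        k <- gap[1L]
        what <- if (b$start[k + 1L] > b$end[k]) "gap" else "overlap"
        stop(sprintf("block map not seamless on %s: %s between blocks '%s' (ends %d) and '%s' (starts %d)",
                     c, what, b$block_id[k], b$end[k], b$block_id[k + 1L], b$start[k + 1L]))
      }
    }
    if (!is.null(chrom_table)) {
      len <- chrom_table$length[match(c, chrom_table$chrom)]
      if (!is.na(len) && (b$start[1L] != 0L || b$end[nrow(b)] != len)) {
        stop(sprintf("blocks on %s cover [%d, %d) but chromosome length is %d",
                     c, b$start[1L], b$end[nrow(b)], len))
      }
    }
  }
  class(df) <- c("g2h_blockmap", "data.frame")
  df
}

#' Read a chromosome table
#'
#' TSV with header columns `chrom`, `length_bp` and optionally
#' `genetic_length_cM` (used only by the simulator).
#'
#' @param path path to the TSV file.
#' @return data.frame with `chrom`, `length` (bp) and optional
#'   `genetic_length` (cM).
#' @export
read_chrom_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  out <- data.frame(chrom = as.character(df$chrom),
                    length = as.numeric(df$length_bp), stringsAsFactors = FALSE)
  if ("genetic_length_cM" %in% names(df)) {
    out$genetic_length <- as.numeric(df$genetic_length_cM)
    if (any(out$genetic_length <= 0)) stop("genetic_length_cM must be > 0")
  }
  if (any(out$length <= 0)) stop("chromosome length must be > 0")
  out
}

#' Chromosome lengths implied by a block map
#'
#' Blocks tile each chromosome, so the end of the last block is the chromosome
#' length.
#'
#' @param blocks a `g2h_blockmap`.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths_from_blocks <- function(blocks) {
  vapply(split(blocks$end, factor(blocks$chrom, levels = unique(blocks$chrom))),
         max, numeric(1))
}

fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

write_tsv_fixed <- function(df, path, num_cols = NULL, digits = 6L) {
  op <- options(scipen = 15)  # fixed notation for coordinate columns
  on.exit(options(op))
  for (cn in intersect(num_cols, names(df))) df[[cn]] <- fmt_num(df[[cn]], digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-individual recovery reports, segments and breakpoints
#'
#' Writes `summary.tsv` (one row per individual: PRPG, HTBR, WGBR, fragment
#' count, CFDI, high-recovery flag), `segments.tsv` (1-based inclusive
#' coordinates), `breakpoints.tsv` and `fragments.tsv`. Rates are printed with
#' six decimals so that re-reading reproduces the in-memory values to that
#' precision.
#'
#' @param reports recovery report data.frame (see [run_pipeline()]).
#' @param segments segment data.frame with 0-based half-open `start`/`end`.
#' @param out_dir output directory (created if absent).
#' @param breakpoints optional breakpoint data.frame.
#' @param fragments optional fragment data.frame (0-based half-open).
#' @param ranking optional ranking data.frame.
#' @return invisibly, the vector of files written.
#' @export
write_reports <- function(reports, segments, out_dir, breakpoints = NULL,
                          fragments = NULL, ranking = NULL) {
  if (is.null(reports) || !nrow(reports)) stop("empty report collection")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  written <- character(0)
  p <- file.path(out_dir, "summary.tsv")
  write_tsv_fixed(reports, p, num_cols = c("prpg", "htbr", "wgbr", "cfdi"))
  written <- c(written, p)

  seg_out <- segments
  seg_out$start <- seg_out$start + 1L  # 1-based inclusive on the way out
  p <- file.path(out_dir, "segments.tsv")
  write_tsv_fixed(seg_out[, c("sample", "chrom", "start", "end", "state",
                              "n_blocks", "median_value")],
                  p, num_cols = "median_value")
  written <- c(written, p)

  if (is.null(breakpoints)) {
    breakpoints <- data.frame(sample = character(0), chrom = character(0),
                              left_end = integer(0), right_start = integer(0))
  }
  p <- file.path(out_dir, "breakpoints.tsv")
  write_tsv_fixed(breakpoints, p)
  written <- c(written, p)

  if (is.null(fragments)) {
    fragments <- data.frame(sample = character(0), chrom = character(0),
                            start = integer(0), end = integer(0),
                            length = integer(0))
  } else if (nrow(fragments)) {
    fragments$start <- fragments$start + 1L
  }
  p <- file.path(out_dir, "fragments.tsv")
  write_tsv_fixed(fragments, p)
  written <- c(written, p)

  if (!is.null(ranking)) {
    p <- file.path(out_dir, "ranking.tsv")
    write_tsv_fixed(ranking, p, num_cols = c("prpg", "htbr", "wgbr", "cfdi"))
    written <- c(written, p)
  }
  invisible(written)
}

#' Convert output-convention segments back to internal coordinates
#'
#' Inverse of the coordinate convention used by [write_reports()]: 1-based
#' inclusive intervals become 0-based half-open.
#'
#' @param df data.frame with `start`, `end` columns in 1-based inclusive form.
#' @return the data.frame with 0-based half-open coordinates.
#' @export
segments_to_internal <- function(df) {
  df$start <- df$start - 1L
  df
}
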