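#' Haplotype-block detection parameters
#'
#' Parameters of the confidence-interval block definition.  The defaults are
#' the calibrated setting used throughout the package: strong-LD interval
#' bounds 0.5/0.85, historical-recombination upper bound 0.7 (instead of the
#' Haploview default 0.9), and a 10 Mb scanning window.  `inform_frac` is
#' the minimum share of strong-LD pairs among informative pairs inside an
#' accepted block (0.95, the Haploview convention).
#'
#' @param strong_low minimum D' CI lower bound for a strong-LD pair.
#' @param strong_high minimum D' CI upper bound for a strong-LD pair.
#' @param recomb_high CI upper bound below which a pair shows strong
#'   historical recombination.
#' @param inform_frac minimum strong-LD fraction among informative pairs.
#' @param max_window_bp maximum block span in base pairs.
#' @param min_block_snps minimum SNPs per block.
#' @param ci_confidence coverage of the D' likelihood interval.
#' @param ci_grid_n grid resolution of the D' likelihood profile.
#' @return a list of class `block_config`.
#' @export
block_config <- function(strong_low = 0.5, strong_high = 0.85,
                         recomb_high = 0.7, inform_frac = 0.95,
                         max_window_bp = 10e6, min_block_snps = 2L,
                         ci_confidence = 0.90, ci_grid_n = 101L) {
  stopifnot(strong_low > 0, strong_low < strong_high, strong_high <= 1,
            recomb_high < strong_high, inform_frac > 0, inform_frac <= 1,
            max_window_bp > 0, min_block_snps >= 1)
  structure(
    list(strong_low = strong_low, strong_high = strong_high,
         recomb_high = recomb_high, inform_frac = inform_frac,
         max_window_bp = max_window_bp,
         min_block_snps = as.integer(min_block_snps),
         ci_confidence = ci_confidence, ci_grid_n = as.integer(ci_grid_n)),
    class = "block_config"
  )
}

#' Partition a chromosome into haplotype blocks
#'
#' Confidence-interval block finding: a candidate block is a contiguous run
#' of variants whose outermost pair is itself in strong LD and whose span
#' does not exceed `max_window_bp`; it is accepted when, among its
#' informative pairs (strong LD + strong recombination), the strong-LD
#' fraction reaches `inform_frac`.  Accepted candidates are selected
#' greedily by descending SNP count (ties broken toward the leftmost start),
#' discarding any candidate overlapping an earlier selection.
#'
#' @param g a filtered single-chromosome [genotype_matrix()].
#' @param cfg a [block_config()].
#' @param pairs optionally a precomputed [ld_pairs()] table for `g`.
#' @return a list with `blocks` (tibble: `block_id`, `chrom`, `first_idx`,
#'   `last_idx`, `start_bp`, `end_bp`, `n_snps`, `snp_ids` (list column),
#'   `avg_pairwise_ld`) and `singletons` (integer indices of variants in no
#'   block).
#' @export
find_blocks <- function(g, cfg = block_config(), pairs = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(unique(g$variants$chrom)) > 1L) {
    abort("find_blocks() works on one chromosome at a time; split the input")
  }
  m <- n_snps(g)
  if (is.null(pairs)) pairs <- ld_pairs(g, cfg)
  pos <- g$variants$pos_bp

  cand <- candidate_spans(pairs, pos, m, cfg)
  chosen <- greedy_select(cand, m)

  blocks <- tibble::tibble(
    block_id = character(0), chrom = character(0),
    first_idx = integer(0), last_idx = integer(0),
    start_bp = integer(0), end_bp = integer(0), n_snps = integer(0),
    snp_ids = list(), avg_pairwise_ld = double(0)
  )
  if (nrow(chosen)) {
    chosen <- chosen[order(chosen$first), ]
    blocks <- tibble::tibble(
      block_id = sprintf("%s_blk%03d", g$variants$chrom[1],
                         seq_len(nrow(chosen))),
      chrom = g$variants$chrom[1],
      first_idx = chosen$first, last_idx = chosen$last,
      start_bp = pos[chosen$first], end_bp = pos[chosen$last],
      n_snps = chosen$last - chosen$first + 1L,
      snp_ids = lapply(seq_len(nrow(chosen)), function(k) {
        g$variants$id[chosen$first[k]:chosen$last[k]]
      }),
      avg_pairwise_ld = vapply(seq_len(nrow(chosen)), function(k) {
        mean_block_r2(pairs, chosen$first[k], chosen$last[k])
      }, numeric(1))
    )
  }
  in_block <- logical(m)
  for (k in seq_len(nrow(blocks))) {
    in_block[blocks$first_idx[k]:blocks$last_idx[k]] <- TRUE
  }
  list(blocks = blocks, singletons = which(!in_block))
}

# Enumerate contiguous candidate spans whose endpoint pair is strong LD,
# whose bp span fits the window, and whose informative pairs are dominated
# by strong LD.  Prefix sums over the pair-class matrices make the
# informative-fraction test O(1) per candidate.
candidate_spans <- function(pairs, pos, m, cfg) {
  none <- data.frame(first = integer(0), last = integer(0), size = integer(0))
  if (m < 2L || nrow(pairs) == 0L) return(none)
  strong <- matrix(0, m, m)
  recomb <- matrix(0, m, m)
  idx <- cbind(pairs$i, pairs$j)
  strong[idx] <- as.numeric(pairs$class == "strong_ld")
  recomb[idx] <- as.numeric(pairs$class == "strong_recomb")
  Ps <- pair_prefix(strong)
  Pr <- pair_prefix(recomb)

  ends <- pairs[pairs$class == "strong_ld", c("i", "j")]
  if (nrow(ends) == 0L) return(none)
  size <- ends$j - ends$i + 1L
  keep <- size >= cfg$min_block_snps & (pos[ends$j] - pos[ends$i]) <= cfg$max_window_bp
  ends <- ends[keep, ]; size <- size[keep]
  if (nrow(ends) == 0L) return(none)
  ns <- span_sum(Ps, ends$i, ends$j)
  nr <- span_sum(Pr, ends$i, ends$j)
  ok <- (ns + nr) > 0 & ns / (ns + nr) >= cfg$inform_frac
  data.frame(first = ends$i[ok], last = ends$j[ok], size = size[ok])
}

# 2-D prefix sum P such that span_sum(P, i, j) counts pairs (x, y) with
# i <= x < y <= j.
pair_prefix <- function(A) {
  B <- apply(A, 2, cumsum)
  if (is.null(dim(B))) B <- matrix(B, nrow = nrow(A))
  t(apply(B, 1, cumsum))
}

span_sum <- function(P, i, j) {
  m <- nrow(P)
  at <- function(r, c) ifelse(r >= 1 & c >= 1, P[cbind(pmax(r, 1), pmax(c, 1))], 0)
  at(j, j) - at(i - 1, j) - at(j, i - 1) + at(i - 1, i - 1)
}

greedy_select <- function(cand, m) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(-cand$size, cand$first), ]
  occupied <- logical(m)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    span <- cand$first[k]:cand$last[k]
    if (!any(occupied[span])) {
      keep[k] <- TRUE
      occupied[span] <- TRUE
    }
  }
  cand[keep, ]
}

mean_block_r2 <- function(pairs, first, last) {
  sel <- pairs$i >= first & pairs$j <= last
  if (!any(sel)) return(NA_real_)
  mean(pairs$r2[sel])
}

#' Within-block average pairwise LD
#'
#' Mean LD over all `choose(size, 2)` variant pairs inside a block; the
#' summary used to decide the per-block bottleneck width.  r-squared is the
#' default measure; D' averaging is available via `measure = "dprime"`.
#'
#' @param g a [genotype_matrix()].
#' @param first_idx,last_idx inclusive column range of the block.
#' @param measure `"r2"` (default) or `"dprime"`.
#' @return a single fraction; `NA` (with a warning) for singleton blocks.
#' @export
average_pairwise_ld <- function(g, first_idx, last_idx, measure = c("r2", "dprime")) {
  measure <- match.arg(measure)
  stopifnot(inherits(g, "genotype_matrix"),
            first_idx >= 1, last_idx <= n_snps(g), first_idx <= last_idx)
  if (first_idx == last_idx) {
    warn("average pairwise LD is undefined for a singleton block")
    return(NA_real_)
  }
  idx <- first_idx:last_idx
  pr <- expand_pairs(length(idx))
  stats <- .ld_pairs_cpp(g$dosages[, idx, drop = FALSE],
                         pr$i - 1L, pr$j - 1L)
  vals <- if (measure == "r2") stats[, "r2"] else stats[, "Dprime"]
  mean(vals)
}

expand_pairs <- function(m) {
  i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(a) (a + 1L):m))
  list(i = i, j = j)
}

#' Write and read haplotype blocks in PLINK-style formats
#'
#' `write_blocks()` emits two files: `<prefix>.blocks` (`* id1 id2 ...` per
#' block) and `<prefix>.blocks.det` (whitespace table with header
#' `CHR BP1 BP2 KB NSNPS SNPS`, SNP ids joined by `|`).  `read_blocks()`
#' reads a `.blocks.det`-dialect file back into a block table, resolving
#' SNP ids against a genotype matrix, so externally produced block calls
#' can be used in place of [find_blocks()].
#'
#' @param blocks a block tibble as returned by [find_blocks()].
#' @param prefix output path prefix.
#' @param path path to a `.blocks.det` file.
#' @param g the [genotype_matrix()] whose variants the file refers to.
#' @return `write_blocks` returns the two file paths invisibly;
#'   `read_blocks` returns a block tibble.
#' @export
write_blocks <- function(blocks, prefix) {
  blocks_path <- paste0(prefix, ".blocks")
  det_path <- paste0(prefix, ".blocks.det")
  lines <- vapply(blocks$snp_ids, function(ids) {
    paste("*", paste(ids, collapse = " "))
  }, character(1))
  writeLines(lines, blocks_path)
  det <- data.frame(
    CHR = blocks$chrom, BP1 = blocks$start_bp, BP2 = blocks$end_bp,
    KB = round((blocks$end_bp - blocks$start_bp + 1) / 1000, 3),
    NSNPS = blocks$n_snps,
    SNPS = vapply(blocks$snp_ids, paste, character(1), collapse = "|")
  )
  readr::write_delim(det, det_path, delim = " ", progress = FALSE)
  invisible(c(blocks_path, det_path))
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path, g) {
  stopifnot(inherits(g, "genotype_matrix"))
  det <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c(CHR = "character", SNPS = "character"))
  snp_ids <- strsplit(det$SNPS, "|", fixed = TRUE)
  missing_ids <- setdiff(unlist(snp_ids), g$variants$id)
  if (length(missing_ids)) {
    abort(paste0("block file refers to SNP id(s) absent from the matrix: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  first_idx <- vapply(snp_ids, function(ids) {
    match(ids[1], g$variants$id)
  }, integer(1))
  last_idx <- vapply(snp_ids, function(ids) {
    match(ids[length(ids)], g$variants$id)
  }, integer(1))
  tibble::tibble(
    block_id = sprintf("%s_blk%03d", det$CHR, seq_len(nrow(det))),
    chrom = det$CHR,
    first_idx = first_idx, last_idx = last_idx,
    start_bp = det$BP1, end_bp = det$BP2,
    n_snps = det$NSNPS, snp_ids = snp_ids,
    avg_pairwise_ld = vapply(seq_along(snp_ids), function(k) {
      if (first_idx[k] < last_idx[k]) {
        average_pairwise_ld(g, first_idx[k], last_idx[k])
      } else NA_real_
    }, numeric(1))
  )
}
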