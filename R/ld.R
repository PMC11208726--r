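#' Two-locus haplotype frequency estimation by EM
#'
#' Estimates the four haplotype frequencies (pAB, pAb, paB, pab) for a pair
#' of biallelic loci from unphased diploid dosages.  All genotype pairs
#' resolve into haplotypes unambiguously except the double heterozygote,
#' whose coupling/repulsion split the EM iterates from a uniform start.
#' Convergence: maximum frequency change below `tol` (default `1e-7`) or
#' `max_iter` iterations; the log-likelihood is non-decreasing across
#' iterations.
#'
#' @param col_i,col_j integer dosage vectors in `{0, 1, 2}` of equal length
#'   (minor-allele dosages).
#' @param tol convergence tolerance on the frequency change.
#' @param max_iter iteration cap.
#' @param trace if `TRUE`, attach the per-iteration log-likelihood.
#' @return a list with `freqs` (named numeric of length 4, summing to 1),
#'   `D`, `Dprime`, `r2`, `niter`, `converged`, `degenerate` (TRUE when
#'   either locus is monomorphic, in which case LD is undefined and the pair
#'   is non-informative) and optionally `loglik`.
#' @export
#' @examples
#' x <- c(0L, 1L, 2L, 0L, 2L)
#' em_haplotype_freqs(x, x)$Dprime  # identical columns: complete LD
em_haplotype_freqs <- function(col_i, col_j, tol = 1e-7, max_iter = 1000,
                               trace = FALSE) {
  counts <- pair_counts(col_i, col_j)
  res <- .em_counts_cpp(counts, tol = tol, max_iter = max_iter, trace = trace)
  pA <- sum(counts * row(counts) - counts) / (2 * sum(counts))
  pB <- sum(counts * col(counts) - counts) / (2 * sum(counts))
  res$degenerate <- pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1
  res
}

pair_counts <- function(col_i, col_j) {
  if (length(col_i) != length(col_j)) {
    abort("dosage vectors must have equal length")
  }
  ok <- !is.na(col_i) & !is.na(col_j)
  counts <- matrix(0, 3, 3)
  tab <- table(factor(col_i[ok], levels = 0:2),
               factor(col_j[ok], levels = 0:2))
  counts[] <- as.numeric(tab)
  counts
}

#' LD statistics from two-locus haplotype frequencies
#'
#' Computes the classical disequilibrium measures from a haplotype
#' frequency vector: `D = pAB - pA*pB`; `D' = |D| / Dmax` with
#' `Dmax = min(pA*(1-pB), (1-pA)*pB)` for positive `D` and
#' `min(pA*pB, (1-pA)*(1-pB))` otherwise; `r2 = D^2 / (pA(1-pA)pB(1-pB))`.
#'
#' @param freqs numeric vector `(pAB, pAb, paB, pab)` summing to 1.
#' @return a list with `D`, `Dprime`, `r2`, and `degenerate` (TRUE when an
#'   allele frequency is 0 or 1, making D'/r2 undefined; both are returned
#'   as `NA`).
#' @export
ld_statistics <- function(freqs) {
  stopifnot(length(freqs) == 4, abs(sum(freqs) - 1) < 1e-6)
  pAB <- freqs[[1]]; pAb <- freqs[[2]]; paB <- freqs[[3]]
  pA <- pAB + pAb
  pB <- pAB + paB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(list(D = 0, Dprime = NA_real_, r2 = NA_real_, degenerate = TRUE))
  }
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (dmax > 0) min(abs(D) / dmax, 1) else 0
  r2 <- min(D^2 / (pA * (1 - pA) * pB * (1 - pB)), 1)
  list(D = D, Dprime = Dprime, r2 = r2, degenerate = FALSE)
}

#' Likelihood-based confidence interval for D'
#'
#' Profiles the two-locus genotype likelihood over a grid of `grid_n`
#' equally spaced D-prime values in `[0, 1]` (allele frequencies held at
#' their sample MLEs, the sign of D taken from the EM point estimate),
#' normalizes the likelihood to a unit mass, and returns equal-tail bounds:
#' `ci_low` is the smallest grid value at which the cumulative mass reaches
#' `(1 - confidence)/2`, `ci_high` the largest grid value whose upper tail
#' mass reaches the same level.  This is the Gabriel-style interval that
#' drives haplotype-block classification.
#'
#' @inheritParams em_haplotype_freqs
#' @param confidence coverage of the interval (default 0.90).
#' @param grid_n number of grid points (default 101).
#' @return a list with `ci_low`, `ci_high`, and `degenerate`; bounds are
#'   `NA` for monomorphic loci.
#' @export
dprime_ci <- function(col_i, col_j, confidence = 0.90, grid_n = 101) {
  counts <- pair_counts(col_i, col_j)
  ci <- .dprime_ci_cpp(counts, confidence = confidence, grid_n = grid_n)
  list(ci_low = unname(ci[1]), ci_high = unname(ci[2]),
       degenerate = unname(is.na(ci[1])))
}

#' Classify a SNP pair from its D' confidence interval
#'
#' Implements the confidence-interval pair classes of the Gabriel block
#' definition: a pair is in *strong LD* when the interval lower bound is at
#' least `strong_low` and the upper bound at least `strong_high`; it shows
#' *strong historical recombination* when the upper bound falls below
#' `recomb_high`; any other pair (including degenerate ones) is
#' *non-informative*.
#'
#' @param ci_low,ci_high D' confidence bounds (possibly `NA` for degenerate
#'   pairs).
#' @param cfg a [block_config()].
#' @return one of `"strong_ld"`, `"strong_recomb"`, `"noninformative"`
#'   (vectorized over the inputs).
#' @export
#' @examples
#' cfg <- block_config()
#' classify_pair(0.55, 0.95, cfg)  # strong_ld
#' classify_pair(0.10, 0.65, cfg)  # strong_recomb
classify_pair <- function(ci_low, ci_high, cfg = block_config()) {
  out <- rep("noninformative", length(ci_low))
  ok <- !is.na(ci_low) & !is.na(ci_high)
  out[ok & ci_low >= cfg$strong_low & ci_high >= cfg$strong_high] <- "strong_ld"
  out[ok & ci_high < cfg$recomb_high &
        !(ci_low >= cfg$strong_low & ci_high >= cfg$strong_high)] <-
    "strong_recomb"
  out
}

#' Pairwise LD table for a genotype matrix
#'
#' Computes D, D', r-squared, the D' confidence interval and the Gabriel
#' pair class for every variant pair within `max_window_bp` (or all pairs
#' when `window` is `FALSE`).  The heavy lifting runs in compiled code; one
#' row per pair is returned.
#'
#' @param g a filtered [genotype_matrix()] (single chromosome, no missing
#'   entries).
#' @param cfg a [block_config()].
#' @param window apply the `max_window_bp` pair distance cutoff (default
#'   `TRUE`).
#' @return a tibble with columns `i`, `j` (column indices, `i < j`),
#'   `id_i`, `id_j`, `D`, `Dprime`, `r2`, `ci_low`, `ci_high`, `class`.
#' @export
ld_pairs <- function(g, cfg = block_config(), window = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- n_snps(g)
  if (m < 2L) {
    return(tibble::tibble(
      i = integer(), j = integer(), id_i = character(), id_j = character(),
      D = double(), Dprime = double(), r2 = double(),
      ci_low = double(), ci_high = double(), class = character()
    ))
  }
  if (length(unique(g$variants$chrom)) > 1L) {
    abort("ld_pairs() expects a single chromosome; split the input first")
  }
  pos <- g$variants$pos_bp
  pairs <- all_window_pairs(pos, if (window) cfg$max_window_bp else Inf)
  stats <- .ld_pairs_cpp(g$dosages, pairs$i - 1L, pairs$j - 1L,
                         confidence = cfg$ci_confidence,
                         grid_n = cfg$ci_grid_n)
  tibble::tibble(
    i = pairs$i, j = pairs$j,
    id_i = g$variants$id[pairs$i], id_j = g$variants$id[pairs$j],
    D = stats[, "D"], Dprime = stats[, "Dprime"], r2 = stats[, "r2"],
    ci_low = stats[, "ci_low"], ci_high = stats[, "ci_high"],
    class = classify_pair(stats[, "ci_low"], stats[, "ci_high"], cfg)
  )
}

all_window_pairs <- function(pos, max_window_bp) {
  m <- length(pos)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(m - 1L)) {
    j_max <- max(which(pos - pos[i] <= max_window_bp))
    if (j_max > i) {
      jj <- c(jj, seq.int(i + 1L, j_max))
      ii <- c(ii, rep.int(i, j_max - i))
    }
  }
  list(i = ii, j = jj)
}
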