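# Independent brute-force oracles and fixture builders shared by the suite.
# Every oracle re-derives its answer from first principles (direct likelihood
# evaluation, exhaustive enumeration) without touching the package's
# optimized code paths.

# quick genotype_matrix from a plain dosage matrix
make_gm <- function(dos, pos = NULL, chrom = "22", recode = TRUE) {
  dos <- as.matrix(dos)
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 1000L
  g <- genotype_matrix(
    dos,
    tibble::tibble(
      id = sprintf("s%03d", seq_len(ncol(dos))), chrom = chrom,
      pos_bp = as.integer(pos), ref_allele = "A", alt_allele = "B"
    )
  )
  if (recode) g <- additive_recode(g)
  g
}

# Direct two-locus genotype log-likelihood (written independently of
# src/ld.cpp): counts is a 3x3 table, freqs = (pAB, pAb, paB, pab).
oracle_loglik <- function(counts, freqs) {
  pAB <- freqs[1]; pAb <- freqs[2]; paB <- freqs[3]; pab <- freqs[4]
  P <- matrix(0, 3, 3)
  P[1, 1] <- pab^2;           P[1, 2] <- 2 * pab * paB; P[1, 3] <- paB^2
  P[2, 1] <- 2 * pab * pAb;   P[3, 1] <- pAb^2
  P[2, 2] <- 2 * pAB * pab + 2 * pAb * paB
  P[2, 3] <- 2 * paB * pAB;   P[3, 2] <- 2 * pAb * pAB; P[3, 3] <- pAB^2
  sum(counts[counts > 0] * log(pmax(P[counts > 0], 1e-300)))
}

# Exhaustive-grid likelihood maximizer over D at fixed allele frequencies;
# returns the maximizing haplotype frequencies and D.
oracle_em <- function(col_i, col_j, n_grid = 4001) {
  counts <- table(factor(col_i, levels = 0:2), factor(col_j, levels = 0:2))
  counts <- matrix(as.numeric(counts), 3, 3)
  N <- sum(counts)
  pA <- sum(counts * (row(counts) - 1)) / (2 * N)
  pB <- sum(counts * (col(counts) - 1)) / (2 * N)
  d_lo <- -min(pA * pB, (1 - pA) * (1 - pB))
  d_hi <- min(pA * (1 - pB), (1 - pA) * pB)
  ds <- seq(d_lo, d_hi, length.out = n_grid)
  lls <- vapply(ds, function(d) {
    f <- c(pA * pB + d, pA * (1 - pB) - d, (1 - pA) * pB - d,
           (1 - pA) * (1 - pB) + d)
    oracle_loglik(counts, pmax(f, 0))
  }, numeric(1))
  best <- which.max(lls)
  d <- ds[best]
  list(D = d, pA = pA, pB = pB,
       freqs = c(pA * pB + d, pA * (1 - pB) - d, (1 - pA) * pB - d,
                 (1 - pA) * (1 - pB) + d))
}

# Exhaustive D' CI oracle: same definition as the spec states, computed
# directly (grid over D' in [0,1], equal-tail mass bounds).
oracle_dprime_ci <- function(col_i, col_j, confidence = 0.90, grid_n = 101) {
  counts <- table(factor(col_i, levels = 0:2), factor(col_j, levels = 0:2))
  counts <- matrix(as.numeric(counts), 3, 3)
  N <- sum(counts)
  pA <- sum(counts * (row(counts) - 1)) / (2 * N)
  pB <- sum(counts * (col(counts) - 1)) / (2 * N)
  d_sign <- sign(oracle_em(col_i, col_j)$D)
  if (d_sign == 0) d_sign <- 1
  dmax <- if (d_sign > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, length.out = grid_n)
  lls <- vapply(grid, function(dp) {
    d <- d_sign * dp * dmax
    f <- pmax(c(pA * pB + d, pA * (1 - pB) - d, (1 - pA) * pB - d,
                (1 - pA) * (1 - pB) + d), 0)
    oracle_loglik(counts, f)
  }, numeric(1))
  mass <- exp(lls - max(lls))
  mass <- mass / sum(mass)
  alpha2 <- (1 - confidence) / 2
  lo <- grid[min(which(cumsum(mass) >= alpha2))]
  hi <- grid[max(which(rev(cumsum(rev(mass))) >= alpha2))]
  c(ci_low = lo, ci_high = hi)
}

# Brute-force block finder: enumerate every contiguous span, apply the
# acceptance predicate directly from a pair-class lookup, then greedy
# selection by size (leftmost on ties).
oracle_find_blocks <- function(g, cfg = block_config()) {
  m <- n_snps(g)
  pos <- g$variants$pos_bp
  cls <- matrix(NA_character_, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (pos[j] - pos[i] > cfg$max_window_bp) next
      ci <- dprime_ci(g$dosages[, i], g$dosages[, j],
                      confidence = cfg$ci_confidence, grid_n = cfg$ci_grid_n)
      cls[i, j] <- classify_pair(ci$ci_low, ci$ci_high, cfg)
    }
  }
  cand <- list()
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i || j - i + 1 < cfg$min_block_snps) next
      if (pos[j] - pos[i] > cfg$max_window_bp) next
      if (is.na(cls[i, j]) || cls[i, j] != "strong_ld") next
      inner <- cls[i:j, i:j]
      n_strong <- sum(inner == "strong_ld", na.rm = TRUE)
      n_recomb <- sum(inner == "strong_recomb", na.rm = TRUE)
      if (n_strong + n_recomb == 0) next
      if (n_strong / (n_strong + n_recomb) >= cfg$inform_frac) {
        cand[[length(cand) + 1]] <- c(first = i, last = j, size = j - i + 1)
      }
    }
  }
  if (!length(cand)) return(data.frame(first = integer(0), last = integer(0)))
  cand <- as.data.frame(do.call(rbind, cand))
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
  sel <- cand[keep, c("first", "last")]
  sel[order(sel$first), , drop = FALSE]
}

# Paired one-sided permutation test oracle for mean(a - b) > 0.
oracle_perm_test <- function(a, b, n_perm = 20000, seed = 1) {
  set.seed(seed)
  d <- a - b
  obs <- mean(d)
  perms <- replicate(n_perm, mean(d * sample(c(-1, 1), length(d), TRUE)))
  mean(perms >= obs)
}

# small deterministic founder block for training tests
fixture_block <- function(n_snps = 10, K = 2, eps = 0, n = 400, seed = 11,
                          maf_floor = 0.05) {
  simulate_block(block_sim_config(n_snps, n_founders = K,
                                  mutation_rate = eps, maf_floor = maf_floor),
                 n, seed = seed)
}

# Frozen width profiles, hand-evaluated from the width rule
# n(l) = bn + (input_dim - bn) * (|l|/(hl+1))^p with halves rounded away
# from zero (p = 0.5 elliptic, 0 rectangular).
WIDTH_CASES <- list(
  list(c(10, 4, 3), "elliptic", c(10, 9, 8, 7, 6, 3, 6, 7, 8, 9, 10)),
  list(c(10, 4, 3), "rectangular", c(10, 10, 10, 10, 10, 3, 10, 10, 10, 10, 10)),
  list(c(10, 2, 1), "elliptic", c(10, 8, 6, 1, 6, 8, 10)),
  list(c(10, 2, 1), "rectangular", c(10, 10, 10, 1, 10, 10, 10)),
  list(c(25, 4, 2), "elliptic", c(25, 23, 20, 17, 12, 2, 12, 17, 20, 23, 25)),
  list(c(25, 4, 2), "rectangular", c(25, 25, 25, 25, 25, 2, 25, 25, 25, 25, 25)),
  list(c(25, 4, 3), "elliptic", c(25, 23, 20, 17, 13, 3, 13, 17, 20, 23, 25)),
  list(c(25, 4, 3), "rectangular", c(25, 25, 25, 25, 25, 3, 25, 25, 25, 25, 25)),
  list(c(30, 5, 10), "elliptic", c(30, 28, 26, 24, 22, 18, 10, 18, 22, 24, 26, 28, 30)),
  list(c(30, 5, 10), "rectangular", c(30, 30, 30, 30, 30, 30, 10, 30, 30, 30, 30, 30, 30)),
  list(c(7, 1, 2), "elliptic", c(7, 6, 2, 6, 7)),
  list(c(7, 1, 2), "rectangular", c(7, 7, 2, 7, 7)),
  list(c(12, 3, 4), "elliptic", c(12, 11, 10, 8, 4, 8, 10, 11, 12)),
  list(c(12, 3, 4), "rectangular", c(12, 12, 12, 12, 4, 12, 12, 12, 12)),
  list(c(100, 4, 3), "elliptic", c(100, 90, 78, 64, 46, 3, 46, 64, 78, 90, 100)),
  list(c(100, 4, 3), "rectangular", c(100, 100, 100, 100, 100, 3, 100, 100, 100, 100, 100)),
  list(c(18, 2, 5), "elliptic", c(18, 16, 13, 5, 13, 16, 18)),
  list(c(18, 2, 5), "rectangular", c(18, 18, 18, 5, 18, 18, 18)),
  list(c(5, 1, 5), "elliptic", c(5, 5, 5, 5, 5)),
  list(c(5, 1, 5), "rectangular", c(5, 5, 5, 5, 5)),
  list(c(64, 3, 2), "elliptic", c(64, 56, 46, 33, 2, 33, 46, 56, 64)),
  list(c(64, 3, 2), "rectangular", c(64, 64, 64, 64, 2, 64, 64, 64, 64))
)
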