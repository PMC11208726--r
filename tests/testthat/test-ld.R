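test_that("EM resolves identical columns into pure coupling haplotypes", {
  x <- c(0L, 1L, 2L, 0L, 2L, 1L, 1L, 0L)
  r <- em_haplotype_freqs(x, x, trace = TRUE)
  expect_equal(unname(r$freqs[["pAb"]]), 0, tolerance = 1e-6)
  expect_equal(unname(r$freqs[["paB"]]), 0, tolerance = 1e-6)
  expect_equal(sum(r$freqs), 1, tolerance = 1e-9)
  expect_equal(r$Dprime, 1, tolerance = 1e-6)
  expect_equal(r$r2, 1, tolerance = 1e-6)
  # log-likelihood never decreases along the EM path
  expect_true(all(diff(r$loglik) >= -1e-9))
})

test_that("a lone double heterozygote is the EM's symmetric fixed point", {
  r <- em_haplotype_freqs(1L, 1L)
  expect_equal(unname(r$freqs), rep(0.25, 4))
  expect_equal(r$D, 0)
})

test_that("independent loci at large n estimate near-zero D", {
  set.seed(71)
  a <- rbinom(10000, 2, 0.35)
  b <- rbinom(10000, 2, 0.2)
  r <- em_haplotype_freqs(a, b)
  expect_lt(abs(r$D), 0.01)
  # and the EM agrees with the exhaustive-grid likelihood maximizer
  o <- oracle_em(a, b)
  expect_lt(abs(r$D - o$D), 1e-3)
})

test_that("EM matches exhaustive-grid likelihood maximization on small pairs", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(c(30, 80, 200), 1)
    a <- rbinom(n, 2, runif(1, 0.1, 0.5))
    # induce correlation for half the cases
    b <- if (rep %% 2 == 0) {
      pmin(pmax(a + rbinom(n, 1, 0.2) - rbinom(n, 1, 0.2), 0), 2)
    } else {
      rbinom(n, 2, runif(1, 0.1, 0.5))
    }
    if (var(a) == 0 || var(b) == 0) next
    r <- em_haplotype_freqs(a, b)
    o <- oracle_em(a, b)
    expect_lt(abs(r$D - o$D), 1e-3)
    expect_lt(max(abs(unname(r$freqs) - o$freqs)), 2e-3)
  }
})

test_that("monomorphic loci are flagged degenerate", {
  r <- em_haplotype_freqs(rep(0L, 10), rbinom(10, 2, 0.5))
  expect_true(r$degenerate)
  expect_true(dprime_ci(rep(0L, 10), rbinom(10, 2, 0.5))$degenerate)
})

test_that("ld_statistics computes D, D-prime and r2 from the definitions", {
  # perfect LD at balanced frequencies
  s <- ld_statistics(c(0.5, 0, 0, 0.5))
  expect_equal(s$D, 0.25)
  expect_equal(s$Dprime, 1)
  expect_equal(s$r2, 1)
  # exact equilibrium
  s2 <- ld_statistics(c(0.12, 0.28, 0.18, 0.42))  # pA=0.4, pB=0.3, pAB=pA*pB
  expect_equal(s2$D, 0, tolerance = 1e-12)
  expect_equal(s2$Dprime, 0)
  expect_equal(s2$r2, 0)
  # hand-computed example: pA=0.6, pB=0.3, pAB=0.25
  s3 <- ld_statistics(c(0.25, 0.35, 0.05, 0.35))
  expect_equal(s3$D, 0.07)
  expect_equal(s3$Dprime, 0.07 / 0.12, tolerance = 1e-12)
  expect_equal(s3$r2, 0.0049 / (0.24 * 0.21), tolerance = 1e-12)
  # degenerate allele frequency
  expect_true(ld_statistics(c(0.5, 0.5, 0, 0))$degenerate)
})

test_that("D-prime is 1 whenever a haplotype class has zero frequency", {
  set.seed(8)
  for (rep in 1:20) {
    f <- runif(3)
    freqs <- c(f / sum(f) , 0)[sample(4)]
    s <- ld_statistics(freqs)
    if (!s$degenerate) expect_equal(s$Dprime, 1, tolerance = 1e-9)
  }
})

test_that("D' CI separates tight LD from independence at n = 500", {
  set.seed(13)
  a <- rbinom(500, 2, 0.3)
  ci_same <- dprime_ci(a, a)
  expect_gte(ci_same$ci_low, 0.85)
  expect_equal(classify_pair(ci_same$ci_low, ci_same$ci_high), "strong_ld")
  b <- rbinom(500, 2, 0.4)
  ci_ind <- dprime_ci(a, b)
  expect_lt(ci_ind$ci_high, 0.7)
  expect_equal(classify_pair(ci_ind$ci_low, ci_ind$ci_high), "strong_recomb")
})

test_that("tiny samples give wide, non-informative intervals", {
  ci <- dprime_ci(c(0L, 1L, 2L, 1L), c(1L, 0L, 2L, 1L))
  expect_lt(ci$ci_low, 0.5)
  expect_gt(ci$ci_high, 0.7)
  expect_equal(classify_pair(ci$ci_low, ci$ci_high), "noninformative")
})

test_that("the CI matches an independently coded likelihood profile", {
  set.seed(23)
  for (rep in 1:6) {
    n <- 150
    a <- rbinom(n, 2, runif(1, 0.15, 0.5))
    b <- pmin(pmax(a + rbinom(n, 1, 0.3) - rbinom(n, 1, 0.3), 0), 2)
    if (var(a) == 0 || var(b) == 0) next
    ci <- dprime_ci(a, b)
    o <- oracle_dprime_ci(a, b)
    expect_equal(ci$ci_low, unname(o["ci_low"]), tolerance = 1e-9)
    expect_equal(ci$ci_high, unname(o["ci_high"]), tolerance = 1e-9)
  }
})

test_that("pair classification follows the CI thresholds", {
  cfg <- block_config()
  expect_equal(classify_pair(0.55, 0.95, cfg), "strong_ld")
  expect_equal(classify_pair(0.5, 0.85, cfg), "strong_ld")    # boundary in
  expect_equal(classify_pair(0.10, 0.65, cfg), "strong_recomb")
  expect_equal(classify_pair(0.30, 0.80, cfg), "noninformative")
  expect_equal(classify_pair(0.49, 0.95, cfg), "noninformative")
  expect_equal(classify_pair(NA, NA, cfg), "noninformative")
  expect_equal(classify_pair(c(0.55, 0.1), c(0.95, 0.65), cfg),
               c("strong_ld", "strong_recomb"))
})

test_that("ld_pairs honours the window and returns bounded statistics", {
  d <- fixture_block(6, K = 3, eps = 0.02, n = 300, seed = 3)
  g <- make_gm(d, pos = c(1e3, 2e3, 3e3, 4e3, 5e3, 30e6))
  tab <- ld_pairs(g, block_config(max_window_bp = 10e6))
  # the far SNP pairs with nothing
  expect_false(any(tab$i == 6 | tab$j == 6))
  expect_equal(nrow(tab), choose(5, 2))
  expect_true(all(tab$Dprime >= 0 & tab$Dprime <= 1))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  ok <- !is.na(tab$ci_low)
  expect_true(all(tab$ci_low[ok] <= tab$ci_high[ok]))
})
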