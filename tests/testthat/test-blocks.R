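test_that("three tightly linked SNPs form a single block", {
  set.seed(31)
  x <- rbinom(400, 2, 0.3)
  g <- make_gm(cbind(x, x, x))
  fb <- find_blocks(g)
  expect_equal(nrow(fb$blocks), 1L)
  expect_equal(fb$blocks$first_idx, 1L)
  expect_equal(fb$blocks$last_idx, 3L)
  expect_equal(fb$blocks$avg_pairwise_ld, 1, tolerance = 1e-9)
  expect_length(fb$singletons, 0L)
})

test_that("perfect correlation beyond the window never blocks", {
  set.seed(32)
  x <- rbinom(500, 2, 0.4)
  g <- make_gm(cbind(x, x), pos = c(1e6, 16e6))  # 15 Mb apart
  fb <- find_blocks(g)  # 10 Mb window
  expect_equal(nrow(fb$blocks), 0L)
  expect_equal(fb$singletons, c(1L, 2L))
})

test_that("panels of independent SNPs yield no blocks", {
  set.seed(33)
  g <- make_gm(matrix(rbinom(6 * 800, 2, 0.3), 800, 6))
  fb <- find_blocks(g)
  expect_equal(nrow(fb$blocks), 0L)
  expect_equal(fb$singletons, 1:6)
})

test_that("find_blocks equals the brute-force enumerator on small panels", {
  set.seed(34)
  for (rep in 1:6) {
    m <- sample(6:12, 1)
    n <- 300
    # mixture: a few correlated clumps plus independent noise columns
    base <- rbinom(n, 2, runif(1, 0.2, 0.45))
    cols <- lapply(seq_len(m), function(k) {
      if (runif(1) < 0.6) {
        pmin(pmax(base + rbinom(n, 1, 0.08) - rbinom(n, 1, 0.08), 0), 2)
      } else {
        rbinom(n, 2, runif(1, 0.15, 0.45))
      }
    })
    g <- make_gm(do.call(cbind, cols))
    fb <- find_blocks(g)
    oracle <- oracle_find_blocks(g)
    expect_equal(nrow(fb$blocks), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(fb$blocks$first_idx, oracle$first)
      expect_equal(fb$blocks$last_idx, oracle$last)
    }
  }
})

test_that("blocks are disjoint, sorted and contiguous; singletons complete the partition", {
  pan <- simulate_panel(panel_sim_config(
    600, lapply(1:5, function(i) block_sim_config(6, n_founders = 2 + i %% 3,
                                                  mutation_rate = 0.01)),
    seed = 35))
  fb <- find_blocks(pan$genotypes)
  b <- fb$blocks
  if (nrow(b) > 1) {
    expect_true(all(diff(b$first_idx) > 0))
    expect_true(all(b$first_idx[-1] > b$last_idx[-nrow(b)]))
  }
  covered <- unlist(mapply(seq, b$first_idx, b$last_idx, SIMPLIFY = FALSE))
  expect_setequal(c(covered, fb$singletons), seq_len(n_snps(pan$genotypes)))
  expect_true(all(b$n_snps >= 2))
})

test_that("tightening strong-LD thresholds never increases blocked SNPs", {
  pan <- simulate_panel(panel_sim_config(
    500, lapply(1:4, function(i) block_sim_config(7, n_founders = 3,
                                                  mutation_rate = 0.02)),
    seed = 36))
  g <- pan$genotypes
  blocked_snps <- function(cfg) {
    fb <- find_blocks(g, cfg)
    sum(fb$blocks$n_snps)
  }
  loose <- blocked_snps(block_config(strong_low = 0.5, strong_high = 0.85))
  tight <- blocked_snps(block_config(strong_low = 0.7, strong_high = 0.9))
  tighter <- blocked_snps(block_config(strong_low = 0.8, strong_high = 0.95))
  expect_gte(loose, tight)
  expect_gte(tight, tighter)
})

test_that("multi-chromosome input is rejected", {
  dos <- matrix(rbinom(40, 2, 0.3), 10, 4)
  v <- tibble::tibble(id = paste0("s", 1:4), chrom = c("21", "21", "22", "22"),
                      pos_bp = c(1e3, 2e3, 1e3, 2e3), ref_allele = "A",
                      alt_allele = "B")
  g <- additive_recode(genotype_matrix(dos, v))
  expect_error(find_blocks(g), "one chromosome")
})

test_that("average pairwise LD matches its definition", {
  set.seed(37)
  x <- rbinom(2000, 2, 0.3)
  g <- make_gm(cbind(x, x, x))
  expect_equal(average_pairwise_ld(g, 1, 3), 1, tolerance = 1e-9)
  # independent columns at large n hover near zero
  g2 <- make_gm(matrix(rbinom(4 * 10000, 2, 0.3), 10000, 4))
  expect_lt(average_pairwise_ld(g2, 1, 4), 0.05)
  # two-SNP block equals that pair's r2
  d <- fixture_block(2, K = 2, eps = 0.05, n = 500, seed = 9)
  g3 <- make_gm(d)
  pair_r2 <- em_haplotype_freqs(g3$dosages[, 1], g3$dosages[, 2])$r2
  expect_equal(average_pairwise_ld(g3, 1, 2), pair_r2, tolerance = 1e-9)
  expect_warning(val <- average_pairwise_ld(g3, 1, 1), "singleton")
  expect_true(is.na(val))
})

test_that("blocks round-trip through the .blocks/.blocks.det formats", {
  pan <- simulate_panel(panel_sim_config(
    500, list(block_sim_config(5, 2, mutation_rate = 0.005),
              block_sim_config(6, 3, mutation_rate = 0.005)), seed = 38))
  fb <- find_blocks(pan$genotypes)
  expect_gt(nrow(fb$blocks), 0)
  prefix <- withr::local_tempfile()
  paths <- write_blocks(fb$blocks, prefix)
  expect_true(all(file.exists(paths)))
  # det KB column is the span in kilobases
  det <- utils::read.table(paths[2], header = TRUE)
  expect_equal(det$KB, (fb$blocks$end_bp - fb$blocks$start_bp + 1) / 1000,
               tolerance = 1e-3)
  rt <- read_blocks(paths[2], pan$genotypes)
  expect_equal(rt$first_idx, fb$blocks$first_idx)
  expect_equal(rt$last_idx, fb$blocks$last_idx)
  expect_equal(rt$n_snps, fb$blocks$n_snps)
  expect_equal(rt$avg_pairwise_ld, fb$blocks$avg_pairwise_ld, tolerance = 1e-9)
})

test_that("block files naming unknown SNPs are rejected", {
  g <- make_gm(matrix(rbinom(40, 2, 0.3), 10, 4))
  det <- data.frame(CHR = "22", BP1 = 1000, BP2 = 2000, KB = 1.001,
                    NSNPS = 2, SNPS = "s001|nonexistent")
  path <- withr::local_tempfile()
  write.table(det, path, row.names = FALSE, quote = FALSE)
  expect_error(read_blocks(path, g), "absent")
})
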