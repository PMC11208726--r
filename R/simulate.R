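#' Configuration for one simulated founder-haplotype block
#'
#' The generator instantiates the structure the compression method relies
#' on: a block harbours `n_founders` distinct founder haplotypes; every
#' individual draws two founders i.i.d. from `founder_freq` and inherits
#' each founder allele with an independent flip probability
#' `mutation_rate`.  SNP columns whose minor allele frequency falls below
#' `maf_floor` are redrawn (bounded retries) so simulated panels pass the
#' common-variant filters untouched.
#'
#' @param n_snps number of SNPs in the block.
#' @param n_founders number of founder haplotypes (K >= 2).
#' @param founder_freq probability vector over founders; `NULL` (default)
#'   draws one from a symmetric Dirichlet (`alpha = 2`) when the block is
#'   simulated.
#' @param mutation_rate per-allele flip probability in `[0, 0.5)`.
#' @param maf_floor minimum column MAF (post-hoc rejection threshold).
#' @param max_retries redraw attempts per column before giving up.
#' @return a list of class `block_sim_config`.
#' @export
block_sim_config <- function(n_snps, n_founders = 4L, founder_freq = NULL,
                             mutation_rate = 0.005, maf_floor = 0.05,
                             max_retries = 100L) {
  stopifnot(n_snps >= 1, n_founders >= 2,
            mutation_rate >= 0, mutation_rate < 0.5,
            maf_floor >= 0, maf_floor < 0.5)
  if (!is.null(founder_freq)) {
    stopifnot(length(founder_freq) == n_founders,
              abs(sum(founder_freq) - 1) < 1e-8, all(founder_freq >= 0))
  }
  structure(list(n_snps = as.integer(n_snps),
                 n_founders = as.integer(n_founders),
                 founder_freq = founder_freq,
                 mutation_rate = mutation_rate, maf_floor = maf_floor,
                 max_retries = as.integer(max_retries)),
            class = "block_sim_config")
}

#' Simulate one founder-haplotype block
#'
#' Draws K binary founder haplotypes (each SNP's minor allele carried by a
#' random founder subset), assigns every individual two founders i.i.d.
#' from the founder distribution, flips inherited alleles with the
#' configured mutation rate, and returns the summed dosages.  Columns are
#' oriented so the counted allele is the minor one, and columns below the
#' MAF floor are redrawn.
#'
#' @param cfg a [block_sim_config()].
#' @param n_samples number of individuals.
#' @param seed integer seed; identical seeds give identical blocks.
#' @return an integer dosage matrix (`n_samples x n_snps`) with attributes
#'   `founders` (K x n_snps binary matrix), `founder_freq`, and
#'   `founder_of` (n_samples x 2 founder picks).
#' @export
simulate_block <- function(cfg, n_samples, seed = 1L) {
  stopifnot(inherits(cfg, "block_sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  K <- cfg$n_founders
  freq <- cfg$founder_freq
  if (is.null(freq)) {
    freq <- stats::rgamma(K, shape = 2)
    freq <- freq / sum(freq)
  }
  f1 <- sample.int(K, n_samples, replace = TRUE, prob = freq)
  f2 <- sample.int(K, n_samples, replace = TRUE, prob = freq)

  founders <- matrix(0L, K, cfg$n_snps)
  dos <- matrix(0L, n_samples, cfg$n_snps)
  for (s in seq_len(cfg$n_snps)) {
    for (attempt in seq_len(cfg$max_retries)) {
      fa <- stats::rbinom(K, 1L, 0.5)
      a1 <- fa[f1]
      a2 <- fa[f2]
      if (cfg$mutation_rate > 0) {
        a1 <- xor(a1, stats::rbinom(n_samples, 1L, cfg$mutation_rate))
        a2 <- xor(a2, stats::rbinom(n_samples, 1L, cfg$mutation_rate))
      }
      d <- as.integer(a1) + as.integer(a2)
      p <- mean(d) / 2
      if (p > 0.5) {  # orient to the minor allele
        d <- 2L - d
        fa <- 1L - fa
        p <- 1 - p
      }
      if (p >= cfg$maf_floor) {
        founders[, s] <- fa
        dos[, s] <- d
        break
      }
      if (attempt == cfg$max_retries) {
        abort(sprintf(
          "could not reach maf_floor %.3f for SNP %d after %d retries; lower the floor or change K",
          cfg$maf_floor, s, cfg$max_retries))
      }
    }
  }
  attr(dos, "founders") <- founders
  attr(dos, "founder_freq") <- freq
  attr(dos, "founder_of") <- cbind(f1, f2)
  dos
}

#' Configuration for a simulated multi-block panel
#'
#' @param n_samples number of individuals.
#' @param blocks list of [block_sim_config()] objects, one per block.
#' @param inter_block_gap_bp base pairs between consecutive blocks.
#' @param snp_spacing_bp range (min, max) of within-block SNP spacing.
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @param phenotype_frac optional case fraction; when set, case/control
#'   labels are assigned independently of the genotypes.
#' @return a list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_samples, blocks, inter_block_gap_bp = 20000L,
                             snp_spacing_bp = c(200L, 2000L), chrom = "22",
                             seed = 1L, phenotype_frac = NULL) {
  stopifnot(n_samples >= 1, length(blocks) >= 1,
            all(vapply(blocks, inherits, logical(1), "block_sim_config")))
  structure(list(n_samples = as.integer(n_samples), blocks = blocks,
                 inter_block_gap_bp = as.integer(inter_block_gap_bp),
                 snp_spacing_bp = as.integer(snp_spacing_bp),
                 chrom = chrom, seed = as.integer(seed),
                 phenotype_frac = phenotype_frac),
            class = "panel_sim_config")
}

#' Standard synthetic chromosome configuration
#'
#' The package's default test-bed: `n_blocks` founder-haplotype blocks with
#' positively skewed (log-normal) sizes of mean `mean_snps`, founder counts
#' drawn from `k_range` and mutation rates from `mutation_range`, so the
#' within-block average LD spans both sides of the 0.4 selection threshold.
#'
#' @param n_blocks number of blocks.
#' @param n_samples number of individuals.
#' @param mean_snps mean block size in SNPs.
#' @param k_range integer vector of candidate founder counts.
#' @param mutation_range range of per-allele flip probabilities.
#' @param seed integer seed (drives the size/K/rate draws and the panel).
#' @param ... forwarded to [panel_sim_config()].
#' @return a [panel_sim_config()].
#' @export
standard_panel_config <- function(n_blocks = 50L, n_samples = 2000L,
                                  mean_snps = 25, k_range = 2:6,
                                  mutation_range = c(0.001, 0.01),
                                  seed = 1L, ...) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, "standard_panel"))
  sdlog <- 0.4
  sizes <- pmax(5L, as.integer(round_half_away(
    stats::rlnorm(n_blocks, meanlog = log(mean_snps) - sdlog^2 / 2,
                  sdlog = sdlog))))
  ks <- sample(k_range, n_blocks, replace = TRUE)
  eps <- runif(n_blocks, mutation_range[1], mutation_range[2])
  blocks <- lapply(seq_len(n_blocks), function(b) {
    block_sim_config(sizes[b], n_founders = ks[b], mutation_rate = eps[b])
  })
  panel_sim_config(n_samples, blocks, seed = seed, ...)
}

#' Simulate a multi-block genotype panel with known block boundaries
#'
#' Concatenates independently simulated founder-haplotype blocks with
#' positional gaps and returns both the genotype matrix (with MAF and
#' minor-allele orientation populated) and the ground-truth block table
#' for evaluating the block finder.
#'
#' @param cfg a [panel_sim_config()].
#' @return a list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (tibble: `block`, `first_idx`, `last_idx`, `start_bp`, `end_bp`,
#'   `n_snps`, `n_founders`, `mutation_rate`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))

  n_blocks <- length(cfg$blocks)
  dosage_list <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    dosage_list[[b]] <- simulate_block(cfg$blocks[[b]], cfg$n_samples,
                                       seed = derive_seed(cfg$seed,
                                                          paste0("block", b)))
  }

  set.seed(derive_seed(cfg$seed, "positions"))
  sizes <- vapply(cfg$blocks, function(x) x$n_snps, integer(1))
  pos <- integer(0)
  truth_first <- integer(n_blocks); truth_last <- integer(n_blocks)
  cur <- 1L
  for (b in seq_len(n_blocks)) {
    gaps <- sample(seq.int(cfg$snp_spacing_bp[1], cfg$snp_spacing_bp[2]),
                   sizes[b], replace = TRUE)
    block_pos <- cur + cumsum(gaps) - gaps[1]
    truth_first[b] <- length(pos) + 1L
    truth_last[b] <- length(pos) + sizes[b]
    pos <- c(pos, block_pos)
    cur <- block_pos[length(block_pos)] + cfg$inter_block_gap_bp
  }

  dos <- do.call(cbind, dosage_list)
  variants <- tibble::tibble(
    id = sprintf("rs%06d", seq_along(pos)),
    chrom = cfg$chrom, pos_bp = as.integer(pos),
    ref_allele = "A", alt_allele = "B"
  )
  phenotype <- NULL
  if (!is.null(cfg$phenotype_frac)) {
    set.seed(derive_seed(cfg$seed, "phenotype"))
    phenotype <- ifelse(runif(cfg$n_samples) < cfg$phenotype_frac,
                        "case", "control")
  }
  g <- genotype_matrix(dos, variants, phenotype = phenotype)
  g <- additive_recode(g)
  truth <- tibble::tibble(
    block = seq_len(n_blocks),
    first_idx = truth_first, last_idx = truth_last,
    start_bp = as.integer(pos[truth_first]),
    end_bp = as.integer(pos[truth_last]),
    n_snps = sizes,
    n_founders = vapply(cfg$blocks, function(x) x$n_founders, integer(1)),
    mutation_rate = vapply(cfg$blocks, function(x) x$mutation_rate, numeric(1))
  )
  list(genotypes = g, truth = truth)
}

#' Tune a block configuration toward a target internal LD
#'
#' Adjusts the founder count and mutation rate until the simulated average
#' pairwise r-squared lands within `tol` of `target_avg_ld`: for each
#' candidate K (ascending), the mutation rate is bisected (average LD is
#' decreasing in the flip rate at fixed K).  Errors if no candidate reaches
#' the target, reporting the closest achieved value.
#'
#' @param cfg a starting [block_sim_config()].
#' @param target_avg_ld desired average pairwise r-squared in (0, 1).
#' @param n_probe samples per probe simulation.
#' @param seed integer seed for the probes.
#' @param tol acceptance half-width (default 0.05).
#' @param k_candidates founder counts tried in order.
#' @return the tuned [block_sim_config()] with attribute `achieved_ld`.
#' @export
calibrate_ld <- function(cfg, target_avg_ld, n_probe = 1000L, seed = 1L,
                         tol = 0.05, k_candidates = 2:10) {
  stopifnot(target_avg_ld > 0, target_avg_ld < 1)
  probe_ld <- function(k, eps, probe_seed) {
    # uniform founder frequencies: the calibrated structure should carry
    # across seeds, so the free Dirichlet draw is pinned here
    c2 <- block_sim_config(cfg$n_snps, n_founders = k,
                           founder_freq = rep(1 / k, k), mutation_rate = eps,
                           maf_floor = cfg$maf_floor,
                           max_retries = cfg$max_retries)
    # average a few replicates: single draws are noisy for small blocks
    mean(vapply(1:3, function(r) {
      d <- simulate_block(c2, n_probe, seed = derive_seed(probe_seed,
                                                          paste0("rep", r)))
      mean_pairwise_r2(d)
    }, numeric(1)))
  }
  best <- NULL
  for (k in k_candidates) {
    s_k <- derive_seed(seed, paste0("calibrate_k", k))
    hi_ld <- probe_ld(k, 0, s_k)
    if (is.null(best) || abs(hi_ld - target_avg_ld) < abs(best$ld - target_avg_ld)) {
      best <- list(k = k, eps = 0, ld = hi_ld)
    }
    if (hi_ld + tol < target_avg_ld) next  # even noiseless LD too low
    lo_eps <- 0; hi_eps <- 0.4
    for (it in 1:18) {
      mid <- (lo_eps + hi_eps) / 2
      ld_mid <- probe_ld(k, mid, derive_seed(s_k, paste0("bisect", it)))
      if (abs(ld_mid - target_avg_ld) < abs(best$ld - target_avg_ld)) {
        best <- list(k = k, eps = mid, ld = ld_mid)
      }
      if (abs(ld_mid - target_avg_ld) <= tol) break
      if (ld_mid > target_avg_ld) lo_eps <- mid else hi_eps <- mid
    }
    if (abs(best$ld - target_avg_ld) <= tol) break
  }
  if (abs(best$ld - target_avg_ld) > tol) {
    abort(sprintf(
      "calibrate_ld: target %.2f unreachable; closest achieved %.3f (K=%d, rate=%.4f)",
      target_avg_ld, best$ld, best$k, best$eps))
  }
  out <- block_sim_config(cfg$n_snps, n_founders = best$k,
                          founder_freq = rep(1 / best$k, best$k),
                          mutation_rate = best$eps,
                          maf_floor = cfg$maf_floor,
                          max_retries = cfg$max_retries)
  attr(out, "achieved_ld") <- best$ld
  out
}

#' Convert ground-truth simulation boundaries into a block structure
#'
#' Builds the same structure [find_blocks()] returns from the true block
#' boundaries of [simulate_panel()], with within-block average pairwise LD
#' computed from the genotypes, so pipelines can run on the generator's
#' blocks directly.
#'
#' @param g the simulated [genotype_matrix()].
#' @param truth the `truth` tibble from [simulate_panel()].
#' @return a list with `blocks` and `singletons`, as from [find_blocks()].
#' @export
blocks_from_truth <- function(g, truth) {
  stopifnot(inherits(g, "genotype_matrix"))
  blocks <- tibble::tibble(
    block_id = sprintf("%s_true%03d", g$variants$chrom[1], truth$block),
    chrom = g$variants$chrom[1],
    first_idx = truth$first_idx, last_idx = truth$last_idx,
    start_bp = truth$start_bp, end_bp = truth$end_bp,
    n_snps = truth$n_snps,
    snp_ids = lapply(seq_len(nrow(truth)), function(b) {
      g$variants$id[truth$first_idx[b]:truth$last_idx[b]]
    }),
    avg_pairwise_ld = vapply(seq_len(nrow(truth)), function(b) {
      if (truth$first_idx[b] < truth$last_idx[b]) {
        average_pairwise_ld(g, truth$first_idx[b], truth$last_idx[b])
      } else NA_real_
    }, numeric(1))
  )
  covered <- unlist(lapply(seq_len(nrow(truth)), function(b) {
    truth$first_idx[b]:truth$last_idx[b]
  }))
  list(blocks = blocks, singletons = setdiff(seq_len(n_snps(g)), covered))
}

# average pairwise r2 of a plain dosage matrix (all pairs)
mean_pairwise_r2 <- function(dos) {
  m <- ncol(dos)
  if (m < 2L) return(NA_real_)
  pr <- expand_pairs(m)
  storage.mode(dos) <- "integer"
  stats <- .ld_pairs_cpp(dos, pr$i - 1L, pr$j - 1L)
  mean(stats[, "r2"])
}
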