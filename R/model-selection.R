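#' Per-block hyperparameter grid search under k-fold cross-validation
#'
#' Trains one autoencoder per (bn, hl, shape) grid cell and fold, holding
#' each fold out in turn, and averages validation MSE and SNP accuracy over
#' folds.  The default grid is bn 1-10, hl 1-5, both shapes (100 cells).
#' Cells with `bn > input_dim` are skipped and flagged.  Fold assignment is
#' random from a stream derived from `(seed, block_id)` and is identical
#' across cells, so configurations are compared on the same folds.
#'
#' @param dosages numeric block submatrix (samples x SNPs).
#' @param folds number of cross-validation folds (default 5).
#' @param grid data frame with columns `bn`, `hl`, `shape`; defaults to the
#'   full standard grid.
#' @param recipe a [train_recipe()].
#' @param seed integer seed for fold assignment.
#' @param block_id label for messages/seed derivation.
#' @return a list of class `grid_search_result` with `results` (one row per
#'   grid cell: `bn`, `hl`, `shape`, `cv_mse`, `cv_acc`, `skipped`) and
#'   `best_per_bn` (highest-accuracy configuration at each bn, ties broken
#'   toward smaller `hl`, then the elliptic shape).
#' @export
grid_search_block <- function(dosages, folds = 5L, grid = NULL,
                              recipe = train_recipe(), seed = 1L,
                              block_id = "block") {
  X <- as.matrix(dosages)
  n <- nrow(X)
  if (n < folds) abort("block must have at least `folds` samples")
  if (is.null(grid)) {
    grid <- expand.grid(bn = 1:10, hl = 1:5,
                        shape = c("elliptic", "rectangular"),
                        stringsAsFactors = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, paste0("folds:", block_id)))
  fold_of <- sample(rep_len(seq_len(folds), n))

  rows <- purrr::pmap(grid, function(bn, hl, shape) {
    if (bn > ncol(X)) {
      return(tibble::tibble(bn = bn, hl = hl, shape = shape,
                            cv_mse = NA_real_, cv_acc = NA_real_,
                            skipped = TRUE))
    }
    spec <- architecture_spec(ncol(X), hl = hl, bn = bn, shape = shape)
    mses <- accs <- numeric(folds)
    for (f in seq_len(folds)) {
      fit <- train_block(spec, X, recipe = recipe,
                         val_idx = which(fold_of == f),
                         block_id = sprintf("%s/bn%d_hl%d_%s_f%d",
                                            block_id, bn, hl, shape, f))
      mses[f] <- fit$val_mse
      accs[f] <- fit$val_acc
    }
    tibble::tibble(bn = bn, hl = hl, shape = shape,
                   cv_mse = mean(mses), cv_acc = mean(accs), skipped = FALSE)
  })
  results <- dplyr::bind_rows(rows)

  best_per_bn <- results |>
    dplyr::filter(!.data$skipped) |>
    dplyr::group_by(.data$bn) |>
    dplyr::arrange(dplyr::desc(.data$cv_acc), .data$hl,
                   .data$shape != "elliptic", .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  structure(list(block_id = block_id, fold_of = fold_of,
                 results = results, best_per_bn = best_per_bn),
            class = "grid_search_result")
}

#' Elbow point of an accuracy-versus-bottleneck curve
#'
#' Formalizes the visual trade-off point as a marginal-gain rule: the elbow
#' is the smallest bn whose accuracy gain to the next bn falls below
#' `min_gain`; if every gain stays at or above `min_gain`, the last bn is
#' returned.  The default threshold (0.002) brackets the marginal-gain
#' scale at which widening the bottleneck stops paying for itself.
#'
#' @param acc_by_bn numeric vector of accuracies ordered by bn = 1, 2, ...
#' @param min_gain marginal accuracy gain below which widening stops.
#' @return the elbow bn (integer index into `acc_by_bn`).
#' @export
#' @examples
#' elbow_point(c(0.90, 0.95, 0.96, 0.9616, 0.9626))
elbow_point <- function(acc_by_bn, min_gain = 0.002) {
  if (length(acc_by_bn) < 2L) abort("need accuracies for at least two bn values")
  if (max(acc_by_bn) < 0.9) {
    warn("maximum accuracy below 0.9; elbow may be unreliable")
  }
  gains <- diff(acc_by_bn)
  below <- which(gains < min_gain)
  if (length(below)) below[1] else length(acc_by_bn)
}

#' Standardized architecture selection rule
#'
#' The compromise configuration applied to every block: elliptic shape,
#' four hidden layers, and a bottleneck of 2 when the block's average
#' pairwise LD exceeds `ld_threshold` (low internal variation) or 3
#' otherwise.  A block whose average LD is exactly at the threshold gets
#' the wider bottleneck (the rule is strict).
#'
#' @param ld_threshold internal-LD cutoff (default 0.4).
#' @param bn_high_ld bottleneck for blocks above the threshold (default 2).
#' @param bn_low_ld bottleneck for blocks at or below it (default 3).
#' @param shape architecture shape (default `"elliptic"`).
#' @param hl hidden layers per side (default 4).
#' @return a list of class `selection_rule`.
#' @export
selection_rule <- function(ld_threshold = 0.4, bn_high_ld = 2L,
                           bn_low_ld = 3L, shape = "elliptic", hl = 4L) {
  stopifnot(ld_threshold > 0, bn_high_ld < bn_low_ld)
  structure(list(ld_threshold = ld_threshold,
                 bn_high_ld = as.integer(bn_high_ld),
                 bn_low_ld = as.integer(bn_low_ld),
                 shape = shape, hl = as.integer(hl)),
            class = "selection_rule")
}

#' Select a block's architecture from its size and internal LD
#'
#' Pure function of the block width and average pairwise LD: applies the
#' [selection_rule()], capping `bn` at the block width.  Singleton blocks
#' (width 1) get a pass-through marker instead of a network spec.
#'
#' @param n_snps block width.
#' @param avg_pairwise_ld the block's mean pairwise r-squared.
#' @param rule a [selection_rule()].
#' @return an [architecture_spec()], or `NULL` with attribute handling via
#'   a `pass_through` flag: the returned object has attribute
#'   `pass_through = TRUE` when no autoencoder should be trained.
#' @export
select_architecture <- function(n_snps, avg_pairwise_ld,
                                rule = selection_rule()) {
  bn <- if (!is.na(avg_pairwise_ld) && avg_pairwise_ld > rule$ld_threshold) {
    rule$bn_high_ld
  } else {
    rule$bn_low_ld
  }
  if (n_snps <= bn) {
    # nothing to compress: keep the block as-is
    out <- list(input_dim = as.integer(n_snps), bn = as.integer(n_snps))
    attr(out, "pass_through") <- TRUE
    return(out)
  }
  spec <- architecture_spec(n_snps, hl = rule$hl, bn = bn, shape = rule$shape)
  attr(spec, "pass_through") <- FALSE
  spec
}

#' One-tailed paired t-test on per-block accuracies
#'
#' Tests whether configuration A attains higher mean accuracy than B over
#' the same blocks (`mean(a - b) > 0`).  Degenerate cases (identical
#' vectors or zero-variance differences) are flagged and reported as not
#' significant.
#'
#' @param acc_a,acc_b paired accuracy vectors (same blocks, same order).
#' @param alpha significance level.
#' @return a tibble with `t`, `df`, `p`, `significant`, `degenerate`.
#' @export
paired_one_tailed_ttest <- function(acc_a, acc_b, alpha = 0.05) {
  if (length(acc_a) != length(acc_b)) abort("accuracy vectors must be paired")
  if (length(acc_a) < 2L) abort("need at least two pairs")
  d <- acc_a - acc_b
  if (sd(d) == 0) {
    return(tibble::tibble(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                          significant = FALSE, degenerate = TRUE))
  }
  ht <- t.test(acc_a, acc_b, paired = TRUE, alternative = "greater")
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, significant = ht$p.value < alpha,
                 degenerate = FALSE)
}
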