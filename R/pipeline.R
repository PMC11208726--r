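#' End-to-end run configuration
#'
#' Bundles every knob of a compression run: the seed, the block-detection
#' parameters, the architecture selection rule, the training recipe and the
#' train/test split.  The split is either an explicit list of held-out
#' sample ids (mirroring a stratum-based holdout) or a seeded random
#' fraction.  Held-out samples are never seen by any autoencoder or PCA
#' fit.
#'
#' @param seed master seed; all derived randomness (splits, shuffling,
#'   simulation) flows from it.
#' @param block_cfg a [block_config()].
#' @param rule a [selection_rule()].
#' @param recipe a [train_recipe()]; defaults to the standard recipe with
#'   its seed tied to `seed`.
#' @param test_frac fraction of samples held out (used when `test_ids` is
#'   `NULL`).
#' @param test_ids explicit character vector of held-out sample ids.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, block_cfg = block_config(),
                       rule = selection_rule(),
                       recipe = train_recipe(seed = seed),
                       test_frac = 0.2, test_ids = NULL) {
  stopifnot(test_frac >= 0, test_frac < 1)
  structure(list(seed = as.integer(seed), block_cfg = block_cfg,
                 rule = rule, recipe = recipe,
                 test_frac = test_frac, test_ids = test_ids),
            class = "run_config")
}

#' Chromosome-wide reconstruction accuracy
#'
#' Block-size-weighted mean of per-block accuracies:
#' `sum(a_i * b_i) / sum(b_i)`.  Identical to pooling every per-variant
#' correctness indicator across the chromosome and averaging.
#'
#' @param block_accs per-block SNP accuracies `a_i` in `[0, 1]`.
#' @param block_sizes per-block SNP counts `b_i` (>= 1).
#' @return a single fraction.
#' @export
#' @examples
#' chromosome_reconstruction_accuracy(c(1.0, 0.5), c(10, 30))  # 0.625
chromosome_reconstruction_accuracy <- function(block_accs, block_sizes) {
  if (length(block_accs) == 0L) abort("no blocks: accuracy undefined")
  if (length(block_accs) != length(block_sizes)) {
    abort("block_accs and block_sizes must have equal length")
  }
  if (any(block_sizes < 1)) abort("block sizes must be >= 1")
  sum(block_accs * block_sizes) / sum(block_sizes)
}

split_samples <- function(g, run) {
  n <- n_samples(g)
  if (!is.null(run$test_ids)) {
    test_idx <- match(run$test_ids, g$sample_ids)
    if (anyNA(test_idx)) abort("test_ids contains unknown sample ids")
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(derive_seed(run$seed, "train_test_split"))
    test_idx <- sample.int(n, size = round(run$test_frac * n))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(intersect(train_idx, test_idx))) {
    abort("internal error: train/test overlap")  # leakage guard
  }
  list(train = train_idx, test = sort(test_idx))
}

# Assemble the per-block processing units: detected blocks plus singleton
# SNPs carried through uncompressed.
block_units <- function(g, blocks_found) {
  blocks <- blocks_found$blocks
  units <- vector("list", nrow(blocks) + length(blocks_found$singletons))
  k <- 0L
  for (b in seq_len(nrow(blocks))) {
    k <- k + 1L
    units[[k]] <- list(block_id = blocks$block_id[b],
                       first_idx = blocks$first_idx[b],
                       last_idx = blocks$last_idx[b],
                       avg_ld = blocks$avg_pairwise_ld[b])
  }
  for (s in blocks_found$singletons) {
    k <- k + 1L
    units[[k]] <- list(block_id = sprintf("%s_snp%06d", g$variants$chrom[1], s),
                       first_idx = s, last_idx = s, avg_ld = NA_real_)
  }
  units[order(vapply(units, function(u) u$first_idx, integer(1)))]
}

acc_metrics <- function(pred, truth, phenotype = NULL) {
  m <- snp_accuracy(pred, truth)
  out <- list(mse = mean((pred - truth)^2), acc = m$overall,
              acc_d0 = m$by_dosage[["0"]], acc_d1 = m$by_dosage[["1"]],
              acc_d2 = m$by_dosage[["2"]])
  if (!is.null(phenotype)) {
    for (ph in unique(phenotype)) {
      rows <- phenotype == ph
      out[[paste0("acc_", ph)]] <-
        snp_accuracy(pred[rows, , drop = FALSE],
                     truth[rows, , drop = FALSE])$overall
    }
  }
  out
}

perfect_metrics <- function(truth, phenotype = NULL) {
  # pass-through blocks reproduce their input exactly
  acc_metrics(truth, truth, phenotype)
}

#' Compress a genotype panel with per-block autoencoders
#'
#' The full workflow on one chromosome: find haplotype blocks (or take
#' them as given), pick each block's architecture with the standardized
#' selection rule, train one autoencoder per block on the training samples
#' only, emit bottleneck embeddings for all samples, and report
#' reconstruction metrics separately for training and held-out samples
#' (overall, per dosage value, and per phenotype group when labels are
#' present).  Blocks too small to compress (width <= bn) and singleton
#' SNPs are passed through uncompressed with a ratio of 1.
#'
#' @param g a filtered single-chromosome [genotype_matrix()].
#' @param run a [run_config()].
#' @param blocks optional precomputed block structure (a [find_blocks()]
#'   result); found from `g` when `NULL`.
#' @return a list of class `compression_result`: `report` (per-block
#'   tibble), `summary` (chromosome aggregates: Eq.-style weighted
#'   accuracies, total compression ratio, means and standard deviations),
#'   `embeddings` (samples x total compressed dims), `column_map`,
#'   `models`, `split`, `blocks`, `run`.
#' @export
compress <- function(g, run = run_config(), blocks = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosages)) abort("genotypes contain missing calls; filter first")
  if (length(unique(g$variants$chrom)) > 1L) {
    abort("compress() processes one chromosome at a time")
  }
  if (is.null(blocks)) blocks <- find_blocks(g, run$block_cfg)
  split <- split_samples(g, run)
  units <- block_units(g, blocks)

  fitted <- lapply(units, function(u) {
    fit_unit_ae(g, u, run, split)
  })
  report <- dplyr::bind_rows(lapply(fitted, function(f) f$row))
  emb <- do.call(cbind, lapply(fitted, function(f) f$embedding))
  offsets <- cumsum(c(0L, vapply(fitted, function(f) ncol(f$embedding),
                                 integer(1))))
  column_map <- tibble::tibble(
    block_id = vapply(fitted, function(f) f$row$block_id, character(1)),
    first_col = offsets[-length(offsets)] + 1L,
    last_col = offsets[-1L]
  )
  models <- lapply(fitted, function(f) f$model)
  names(models) <- column_map$block_id

  structure(list(report = report,
                 summary = summarize_report(report),
                 embeddings = emb, column_map = column_map, models = models,
                 split = split, blocks = blocks, run = run),
            class = "compression_result")
}

fit_unit_ae <- function(g, u, run, split) {
  idx <- u$first_idx:u$last_idx
  X <- g$dosages[, idx, drop = FALSE]
  storage.mode(X) <- "double"
  Xtr <- X[split$train, , drop = FALSE]
  Xte <- X[split$test, , drop = FALSE]
  ph_tr <- g$phenotype[split$train]
  ph_te <- g$phenotype[split$test]
  spec <- select_architecture(length(idx), u$avg_ld, run$rule)

  if (isTRUE(attr(spec, "pass_through"))) {
    row <- c(list(block_id = u$block_id, first_idx = u$first_idx,
                  last_idx = u$last_idx, n_snps = length(idx),
                  bn = length(idx), avg_ld = u$avg_ld, method = "AE",
                  pass_through = TRUE, ratio = 1),
             prefix_names(perfect_metrics(Xtr, ph_tr), "train_"),
             prefix_names(perfect_metrics(Xte, ph_te), "test_"))
    return(list(row = tibble::as_tibble(row), embedding = X, model = NULL))
  }

  fit <- tryCatch(
    train_block(spec, Xtr, recipe = run$recipe, val_frac = 0,
                block_id = u$block_id),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warn(sprintf("block '%s' failed to train (%s); passing through",
                 u$block_id, conditionMessage(fit)))
    row <- c(list(block_id = u$block_id, first_idx = u$first_idx,
                  last_idx = u$last_idx, n_snps = length(idx),
                  bn = length(idx), avg_ld = u$avg_ld, method = "AE",
                  pass_through = TRUE, ratio = 1),
             prefix_names(perfect_metrics(Xtr, ph_tr), "train_"),
             prefix_names(perfect_metrics(Xte, ph_te), "test_"))
    return(list(row = tibble::as_tibble(row), embedding = X, model = NULL))
  }

  tr_metrics <- acc_metrics(reconstruct(fit, Xtr), Xtr, ph_tr)
  te_metrics <- acc_metrics(reconstruct(fit, Xte), Xte, ph_te)
  row <- c(list(block_id = u$block_id, first_idx = u$first_idx,
                last_idx = u$last_idx, n_snps = length(idx),
                bn = spec$bn, avg_ld = u$avg_ld, method = "AE",
                pass_through = FALSE,
                ratio = compression_ratio(spec$bn, spec$input_dim)),
           prefix_names(tr_metrics, "train_"),
           prefix_names(te_metrics, "test_"))
  list(row = tibble::as_tibble(row), embedding = encode(fit, X), model = fit)
}

prefix_names <- function(x, prefix) {
  names(x) <- paste0(prefix, names(x))
  x
}

summarize_report <- function(report) {
  by_method <- split(report, report$method)
  lapply(by_method, function(rep) {
    list(
      n_blocks = nrow(rep),
      n_snps = sum(rep$n_snps),
      total_compressed_dims = sum(rep$bn),
      total_compression_ratio = sum(rep$bn) / sum(rep$n_snps),
      chromosome_accuracy_train =
        chromosome_reconstruction_accuracy(rep$train_acc, rep$n_snps),
      chromosome_accuracy_test =
        chromosome_reconstruction_accuracy(rep$test_acc, rep$n_snps),
      mean_train_acc = mean(rep$train_acc), sd_train_acc = sd(rep$train_acc),
      mean_test_acc = mean(rep$test_acc), sd_test_acc = sd(rep$test_acc),
      mean_train_mse = mean(rep$train_mse), sd_train_mse = sd(rep$train_mse),
      mean_test_mse = mean(rep$test_mse), sd_test_mse = sd(rep$test_mse)
    )
  })
}

#' Head-to-head comparison of autoencoder and PCA compression
#'
#' Runs [compress()] and, for every block, fits a PCA baseline with latent
#' dimension equal to the block's bottleneck on the same training samples,
#' computing identical metrics on identical splits.  The report gains PCA
#' rows; the summary carries both methods' chromosome-wide accuracies and
#' their paired difference.
#'
#' @inheritParams compress
#' @return a `compression_result` whose `report` holds `AE` and `PCA` rows
#'   and whose `summary` includes `accuracy_gap_test` /
#'   `accuracy_gap_train` (AE minus PCA, in fractions).
#' @export
compare_methods <- function(g, run = run_config(), blocks = NULL) {
  res <- compress(g, run, blocks)
  split <- res$split
  ph_tr <- g$phenotype[split$train]
  ph_te <- g$phenotype[split$test]

  pca_rows <- lapply(seq_len(nrow(res$report)), function(r) {
    row <- res$report[r, ]
    idx <- row$first_idx:row$last_idx
    X <- g$dosages[, idx, drop = FALSE]
    storage.mode(X) <- "double"
    Xtr <- X[split$train, , drop = FALSE]
    Xte <- X[split$test, , drop = FALSE]
    if (row$pass_through) {
      out <- c(list(block_id = row$block_id, first_idx = row$first_idx,
                    last_idx = row$last_idx, n_snps = row$n_snps,
                    bn = row$bn, avg_ld = row$avg_ld, method = "PCA",
                    pass_through = TRUE, ratio = 1),
               prefix_names(perfect_metrics(Xtr, ph_tr), "train_"),
               prefix_names(perfect_metrics(Xte, ph_te), "test_"))
      return(tibble::as_tibble(out))
    }
    k <- min(row$bn, nrow(Xtr) - 1L, ncol(Xtr))
    pm <- fit_pca(Xtr, k, block_id = row$block_id)
    tr <- acc_metrics(pca_reconstruct(pm, Xtr), Xtr, ph_tr)
    te <- acc_metrics(pca_reconstruct(pm, Xte), Xte, ph_te)
    out <- c(list(block_id = row$block_id, first_idx = row$first_idx,
                  last_idx = row$last_idx, n_snps = row$n_snps,
                  bn = k, avg_ld = row$avg_ld, method = "PCA",
                  pass_through = FALSE, ratio = k / row$n_snps),
             prefix_names(tr, "train_"), prefix_names(te, "test_"))
    tibble::as_tibble(out)
  })

  res$report <- dplyr::bind_rows(res$report, dplyr::bind_rows(pca_rows))
  res$summary <- summarize_report(res$report)
  res$summary$accuracy_gap_test <-
    res$summary$AE$chromosome_accuracy_test -
    res$summary$PCA$chromosome_accuracy_test
  res$summary$accuracy_gap_train <-
    res$summary$AE$chromosome_accuracy_train -
    res$summary$PCA$chromosome_accuracy_train
  res
}

#' Moving-average accuracy curves over block size
#'
#' Orders blocks by SNP count and smooths each method's accuracies (overall
#' and per dosage, train and test) with a trailing-centred moving average,
#' reproducing accuracy-versus-block-size curves as tables.
#'
#' @param report a `compression_result$report` tibble.
#' @param window moving-average window in blocks (default 50).
#' @return a tibble sorted by block size with `ma_`-prefixed columns.
#' @export
moving_average_curves <- function(report, window = 50L) {
  cols <- intersect(c("train_acc", "test_acc", "train_acc_d0", "test_acc_d0",
                      "train_acc_d1", "test_acc_d1", "train_acc_d2",
                      "test_acc_d2"), names(report))
  report |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(.data$n_snps, .by_group = TRUE) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(cols),
      ~ moving_avg(.x, window),
      .names = "ma_{.col}"
    )) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("block_id", "method", "n_snps", cols)),
                  dplyr::starts_with("ma_"))
}

moving_avg <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Write a compression report to disk
#'
#' Emits `report.tsv` (per-block table), `summary.json` (chromosome
#' aggregates), `embeddings.tsv` + `column_map.tsv` (when embeddings are
#' present) and `curves.tsv` (moving-average accuracy curves).  All numbers
#' round-trip through the text formats.
#'
#' @param res a `compression_result`.
#' @param dir output directory (created if needed).
#' @param embeddings also write the embedding matrix (default `TRUE`).
#' @return the directory path, invisibly.
#' @export
write_report <- function(res, dir, embeddings = TRUE) {
  stopifnot(inherits(res, "compression_result"))
  if (nrow(res$report) == 0L) abort("empty report: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$report |> dplyr::select(-dplyr::any_of("snp_ids")),
                   file.path(dir, "report.tsv"), progress = FALSE)
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(moving_average_curves(res$report),
                   file.path(dir, "curves.tsv"), progress = FALSE)
  if (embeddings && !is.null(res$embeddings)) {
    emb <- as.data.frame(res$embeddings)
    names(emb) <- sprintf("dim%04d", seq_along(emb))
    readr::write_tsv(emb, file.path(dir, "embeddings.tsv"), progress = FALSE)
    readr::write_tsv(res$column_map, file.path(dir, "column_map.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @export
print.compression_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<compression_result> %d unit(s), %d SNPs\n",
              s$AE$n_blocks, s$AE$n_snps))
  cat(sprintf("  compression ratio %.4f | chr accuracy train %.4f test %.4f (AE)\n",
              s$AE$total_compression_ratio, s$AE$chromosome_accuracy_train,
              s$AE$chromosome_accuracy_test))
  if (!is.null(s$PCA)) {
    cat(sprintf("  PCA chr accuracy train %.4f test %.4f (gap %.4f test)\n",
                s$PCA$chromosome_accuracy_train, s$PCA$chromosome_accuracy_test,
                s$accuracy_gap_test))
  }
  invisible(x)
}
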