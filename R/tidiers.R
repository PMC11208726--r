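#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained block model into its per-epoch training history
#'
#' @param x a [train_block()] result.
#' @param ... ignored.
#' @return a tibble with `epoch` and `train_mse`.
#' @export
tidy.trained_block_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), train_mse = x$history)
}

#' One-row summary of a trained block model
#'
#' @param x a [train_block()] result.
#' @param ... ignored.
#' @return a tibble with the architecture and final metrics.
#' @export
glance.trained_block_model <- function(x, ...) {
  tibble::tibble(
    block_id = x$block_id, shape = x$spec$shape, hl = x$spec$hl,
    bn = x$spec$bn, input_dim = x$spec$input_dim,
    ratio = compression_ratio(x$spec$bn, x$spec$input_dim),
    train_mse = x$train_mse, val_mse = x$val_mse,
    train_acc = x$train_acc, val_acc = x$val_acc
  )
}

#' Tidy a grid-search result into one row per configuration
#'
#' @param x a [grid_search_block()] result.
#' @param ... ignored.
#' @return the per-configuration tibble (`bn`, `hl`, `shape`, `cv_mse`,
#'   `cv_acc`, `skipped`).
#' @export
tidy.grid_search_result <- function(x, ...) x$results

#' One-row summary of a grid search
#'
#' @param x a [grid_search_block()] result.
#' @param ... ignored.
#' @return a tibble with the best configuration and the elbow bottleneck.
#' @export
glance.grid_search_result <- function(x, ...) {
  best <- x$best_per_bn |> dplyr::arrange(dplyr::desc(.data$cv_acc),
                                          .data$bn) |> dplyr::slice(1L)
  acc_by_bn <- x$best_per_bn |> dplyr::arrange(.data$bn) |> dplyr::pull("cv_acc")
  tibble::tibble(
    block_id = x$block_id, n_configs = sum(!x$results$skipped),
    best_bn = best$bn, best_hl = best$hl, best_shape = best$shape,
    best_cv_acc = best$cv_acc,
    elbow_bn = if (length(acc_by_bn) >= 2) elbow_point(acc_by_bn) else NA_integer_
  )
}

#' Tidy a compression result into its per-block report
#'
#' @param x a [compress()] or [compare_methods()] result.
#' @param ... ignored.
#' @return the per-block report tibble.
#' @export
tidy.compression_result <- function(x, ...) x$report

#' One-row-per-method summary of a compression result
#'
#' @param x a [compress()] or [compare_methods()] result.
#' @param ... ignored.
#' @return a tibble with chromosome-wide aggregates per method.
#' @export
glance.compression_result <- function(x, ...) {
  methods <- intersect(names(x$summary), c("AE", "PCA"))
  dplyr::bind_rows(lapply(methods, function(m) {
    s <- x$summary[[m]]
    tibble::tibble(
      method = m, n_blocks = s$n_blocks, n_snps = s$n_snps,
      total_compression_ratio = s$total_compression_ratio,
      chromosome_accuracy_train = s$chromosome_accuracy_train,
      chromosome_accuracy_test = s$chromosome_accuracy_test,
      mean_test_mse = s$mean_test_mse
    )
  }))
}
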