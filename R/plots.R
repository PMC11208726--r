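#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Accuracy-versus-block-size plot for a compression result
#'
#' Scatter of held-out per-block SNP accuracy against block size, one
#' colour per method, with a moving-average trend line.
#'
#' @param object a [compress()] or [compare_methods()] result.
#' @param window moving-average window in blocks.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.compression_result <- function(object, window = 50L, ...) {
  curves <- moving_average_curves(object$report, window)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$n_snps, y = .data$test_acc,
                               colour = .data$method)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ma_test_acc), linewidth = 0.8) +
    ggplot2::labs(x = "Block size (SNPs)", y = "Held-out SNP accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Elbow plot of a grid search
#'
#' Best cross-validated accuracy per bottleneck width, with the detected
#' elbow marked.
#'
#' @param object a [grid_search_block()] result.
#' @param min_gain elbow threshold forwarded to [elbow_point()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.grid_search_result <- function(object, min_gain = 0.002, ...) {
  best <- object$best_per_bn |> dplyr::arrange(.data$bn)
  elbow <- elbow_point(best$cv_acc, min_gain)
  ggplot2::ggplot(best, ggplot2::aes(x = .data$bn, y = .data$cv_acc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best$bn[elbow], linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = best$bn) +
    ggplot2::labs(x = "Bottleneck width (bn)",
                  y = "Best CV SNP accuracy") +
    ggplot2::theme_minimal()
}

#' Per-dosage accuracy summary plot
#'
#' Distribution of per-block held-out accuracies restricted to each true
#' dosage value, by method.
#'
#' @param res a [compress()] or [compare_methods()] result.
#' @return a ggplot object.
#' @export
plot_dosage_accuracy <- function(res) {
  long <- res$report |>
    dplyr::select(dplyr::all_of(c("block_id", "method")),
                  dplyr::starts_with("test_acc_d")) |>
    tidyr::pivot_longer(dplyr::starts_with("test_acc_d"),
                        names_to = "dosage", values_to = "accuracy",
                        names_prefix = "test_acc_d")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dosage, y = .data$accuracy,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "True dosage", y = "Held-out SNP accuracy",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
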