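#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation report
#'
#' One row per fold: confusion counts and the five metrics.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble of per-fold results.
#' @export
tidy.cv_report <- function(x, ...) {
  out <- x$folds
  out$kernel <- x$kernel$kind
  out[c("kernel", setdiff(names(out), "kernel"))]
}

#' Summarise a cross-validation report in one row
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One-row tibble: kernel, number of folds, summed counts and
#'   fold-averaged metrics.
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  bind_cols(tibble(kernel = x$kernel$kind, n_folds = nrow(x$folds)), s)
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object: per-fold metric values with the fold-averaged
#'   level marked.
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[c("fold", "acc", "ppv", "sen", "spe")],
    -"fold", names_to = "metric", values_to = "value")
  avg <- tidyr::pivot_longer(
    object$summary[c("acc", "ppv", "sen", "spe")],
    dplyr::everything(), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = avg,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_x_continuous(breaks = object$folds$fold) +
    ggplot2::labs(x = "fold", y = "percent",
                  title = sprintf("%s kernel: per-fold metrics",
                                  object$kernel$kind)) +
    ggplot2::theme_minimal()
}

#' Plot a kernel comparison table
#'
#' @param object The `table` element of [compare_kernels()] (or a
#'   `stroke_run`'s `comparison`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_kernel_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object[c("kernel", "acc", "ppv", "sen", "spe")],
                              -"kernel", names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$kernel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(50, 100)) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "Fold-averaged performance by SVM kernel") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
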