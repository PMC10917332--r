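#' Plot a linear discriminant fit
#'
#' Training points colored by class, class centroids, and the decision
#' boundary line.
#'
#' @param object An `"lda_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lda_fit <- function(object, ...) {
  d <- object$data
  cen <- tibble::tibble(x = object$centroids[, 1], y = object$centroids[, 2],
                        class = 1:2)
  b <- object$boundary
  slope_ok <- abs(b$direction[1]) > 1e-12
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                       color = factor(.data$class))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = cen, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::labs(color = "class", x = "x", y = "y") +
    ggplot2::theme_minimal()
  if (slope_ok) {
    sl <- b$direction[2] / b$direction[1]
    p <- p + ggplot2::geom_abline(intercept = b$point[2] - sl * b$point[1],
                                  slope = sl, color = "red")
  } else {
    p <- p + ggplot2::geom_vline(xintercept = b$point[1], color = "red")
  }
  p
}

#' Plot the Monte Carlo accuracy histogram
#'
#' Histogram of per-trial training accuracy with the 95% band and the
#' theoretical large-sample accuracy marked.
#'
#' @param object An `"accuracy_experiment"`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_experiment <- function(object, bins = 60, ...) {
  ggplot2::ggplot(tibble::tibble(accuracy = object$samples),
                  ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = c(object$lo, object$hi), linetype = 2) +
    ggplot2::geom_vline(xintercept = object$theoretical, color = "red") +
    ggplot2::labs(x = "training accuracy", y = "trials") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap metric distributions
#'
#' Histograms of the per-run bootstrap metrics with their BCa intervals.
#'
#' @param object A `"pfda_bootstrap"`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfda_bootstrap <- function(object, bins = 50, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              cols = c("accuracy", "balanced_accuracy",
                                       "mcc", "p_rand"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(data = object$intervals,
                        ggplot2::aes(xintercept = .data$lo), linetype = 2) +
    ggplot2::geom_vline(data = object$intervals,
                        ggplot2::aes(xintercept = .data$hi), linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "metric value", y = "runs") +
    ggplot2::theme_minimal()
}

#' Plot a distribution-fit comparison
#'
#' Bar chart of AICc differences per candidate family.
#'
#' @param object A `"dist_fit_comparison"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dist_fit_comparison <- function(object, ...) {
  d <- tidy.dist_fit_comparison(object)
  ggplot2::ggplot(d, ggplot2::aes(stats::reorder(.data$family,
                                                 .data$delta_aicc),
                                  .data$delta_aicc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 2, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "delta AICc") +
    ggplot2::theme_minimal()
}

#' Plot a kernel-density and Q-Q summary
#'
#' Two-panel style plot data: the kernel density with the fitted reference
#' density overlaid, or (with `which = "qq"`) the quantile-quantile points
#' against the identity line.
#'
#' @param object A `"kde_qq_summary"`.
#' @param which `"kde"` or `"qq"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kde_qq_summary <- function(object, which = c("kde", "qq"), ...) {
  which <- match.arg(which)
  if (which == "kde") {
    ref <- tibble::tibble(x = object$kde$x)
    ref$density <- if (object$reference == "normal") {
      dnorm(ref$x, object$params["mean"], object$params["sd"])
    } else {
      stats::dunif(ref$x, object$params["min"], object$params["max"])
    }
    ggplot2::ggplot(object$kde, ggplot2::aes(.data$x, .data$density)) +
      ggplot2::geom_area(fill = "steelblue", alpha = 0.5) +
      ggplot2::geom_line(data = ref, linetype = 2) +
      ggplot2::labs(x = "score", y = "density") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$qq,
                    ggplot2::aes(.data$theoretical, .data$empirical)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_abline(linetype = 2) +
      ggplot2::labs(x = paste(object$reference, "quantiles"),
                    y = "empirical quantiles") +
      ggplot2::theme_minimal()
  }
}
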