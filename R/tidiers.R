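#' Tidy a linear discriminant fit
#'
#' @param x An `"lda_fit"`.
#' @param ... Unused.
#' @return One row per training record: coordinates, class, discriminant
#'   score, class-2 posterior, predicted class.
#' @export
tidy.lda_fit <- function(x, ...) {
  x$data
}

#' One-row summary of a linear discriminant fit
#'
#' @param x An `"lda_fit"`.
#' @param ... Unused.
#' @return Tibble with class sizes, training metrics and centroid
#'   separation.
#' @export
glance.lda_fit <- function(x, ...) {
  m <- classification_metrics(confusion_matrix(x$data$class, x$data$class_pred))
  sep <- sqrt(mahalanobis(x$centroids[2, , drop = FALSE],
                          x$centroids[1, ], x$pooled_cov))
  dplyr::mutate(m, n1 = x$n[1], n2 = x$n[2],
                mahalanobis_separation = unname(sep))
}

#' Per-taxon posterior summary of a pFDA fit
#'
#' Summarizes the per-tree class-2 posteriors of each test taxon: median,
#' 95% percentile band across trees, and the number of trees whose posterior
#' reaches the classification threshold.
#'
#' @param x A `"pfda_fit"` with test taxa.
#' @param ... Unused.
#' @return Tibble: `taxon_id`, `median_p2`, `lo`, `hi`, `n_trees`,
#'   `classified_d2_count`.
#' @export
tidy.pfda_fit <- function(x, ...) {
  if (is.null(x$posteriors)) abort("fit has no test taxa to summarize")
  th <- x$threshold
  x$posteriors |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(
      median_p2 = median(.data$p2),
      lo = quantile(.data$p2, 0.025, names = FALSE),
      hi = quantile(.data$p2, 0.975, names = FALSE),
      n_trees = dplyr::n(),
      classified_d2_count = sum(.data$p2 >= th)
    )
}

#' One-row summary of a pFDA fit
#'
#' @param x A `"pfda_fit"`.
#' @param ... Unused.
#' @return Tibble with tree count, lambda range and median training metrics.
#' @export
glance.pfda_fit <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    lambda_min = min(x$lambda),
    lambda_median = median(x$lambda),
    lambda_max = max(x$lambda),
    median_accuracy = median(x$metrics$accuracy),
    median_balanced_accuracy = median(x$metrics$balanced_accuracy),
    median_mcc = median(x$metrics$mcc),
    median_p_rand = median(x$metrics$p_rand)
  )
}

#' Tidy a pFDA bootstrap
#'
#' @param x A `"pfda_bootstrap"`.
#' @param ... Unused.
#' @return The BCa interval table: one row per metric with median and
#'   interval endpoints.
#' @export
tidy.pfda_bootstrap <- function(x, ...) {
  x$intervals
}

#' One-row summary of a pFDA bootstrap
#'
#' @param x A `"pfda_bootstrap"`.
#' @param ... Unused.
#' @return Tibble with run counts and the accuracy interval.
#' @export
glance.pfda_bootstrap <- function(x, ...) {
  a <- x$intervals[x$intervals$metric == "accuracy", ]
  tibble::tibble(
    n_trials = x$n_trials, trees_per_trial = x$trees_per_trial,
    n_runs = nrow(x$metrics), skipped = x$skipped,
    median_accuracy = a$median, accuracy_lo = a$lo, accuracy_hi = a$hi
  )
}

#' Tidy an accuracy experiment
#'
#' @param x An `"accuracy_experiment"`.
#' @param ... Unused.
#' @return One-row tibble with the 95% band, width and theoretical accuracy.
#' @export
tidy.accuracy_experiment <- function(x, ...) {
  tibble::tibble(n_per_class = x$n_per_class, sigma = x$sigma, d = x$d,
                 trials = x$trials, lo = x$lo, median = x$median, hi = x$hi,
                 width = x$width, theoretical = x$theoretical)
}

#' Tidy a distribution-fit comparison
#'
#' @param x A `"dist_fit_comparison"`.
#' @param ... Unused.
#' @return The comparison table without the params list-column.
#' @export
tidy.dist_fit_comparison <- function(x, ...) {
  tibble::as_tibble(x)[, c("family", "k", "loglik", "aicc", "delta_aicc",
                           "weight", "p_dist", "converged")]
}

#' Tidy a Hopkins result
#'
#' @param x A `"hopkins_result"`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.hopkins_result <- function(x, ...) {
  tibble::tibble(variant = x$variant, H = x$H, m = x$m, n = x$n,
                 reps = x$reps, p_beta = x$p_beta, p_mc = x$p_mc)
}

#' Tidy an allometry fit
#'
#' @param x An `"allometry_fit"`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.allometry_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 x_intercept = x$x_intercept, n = x$n)
}

#' Tidy a BCa interval
#'
#' @param x A `"bca_interval"`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.bca_interval <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, lo = x$lo, hi = x$hi,
                 level = x$level, bias_correction = x$bias_correction,
                 acceleration = x$acceleration, degenerate = x$degenerate)
}
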