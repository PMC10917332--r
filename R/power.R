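#' Class centroids for a given centroid-to-boundary distance
#'
#' The canonical symmetric two-class geometry places the centroids at
#' `(d/sqrt(2)) * (1, -1)` and its reflection, so the decision boundary is
#' the line `y = x` and each centroid sits a distance `d` from it. The
#' default `d = 1.7` corresponds to centroids `(1.2, -1.2)` and
#' `(-1.2, 1.2)`.
#'
#' @param d Centroid-to-boundary distance.
#' @return 2x2 matrix, rows `class1`, `class2`.
#' @export
centroids_for_distance <- function(d = 1.7) {
  h <- d / sqrt(2)
  rbind(class1 = c(h, -h), class2 = c(-h, h))
}

# Training accuracy of one LDA trial on fresh isotropic Gaussian draws.
lda_trial_accuracy <- function(n, sigma, mu1, mu2) {
  repeat {
    X1 <- cbind(rnorm(n, mu1[1], sigma), rnorm(n, mu1[2], sigma))
    X2 <- cbind(rnorm(n, mu2[1], sigma), rnorm(n, mu2[2], sigma))
    m1 <- colMeans(X1); m2 <- colMeans(X2)
    S <- (crossprod(sweep(X1, 2, m1)) + crossprod(sweep(X2, 2, m2))) / (2 * n - 2)
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (is.finite(det_s) && det_s > 1e-12) break
  }
  w <- solve(S, m1 - m2)
  c0 <- sum(w * (m1 + m2)) / 2
  (sum(X1 %*% w > c0) + sum(X2 %*% w < c0)) / (2 * n)
}

#' Monte Carlo distribution of LDA training accuracy
#'
#' Draws `trials` independent two-class datasets (`n_per_class` points per
#' class from isotropic Gaussians with marginal standard deviation `sigma`
#' and centroids a distance `d` from the boundary), fits the linear
#' discriminant to each, and records the training-set accuracy. Reported
#' percentiles are the empirical 2.5/50/97.5 points of that histogram; the
#' theoretical large-sample accuracy is `1 - pwrong(d, sigma)`. Degenerate
#' draws (singular pooled covariance) are redrawn.
#'
#' @param n_per_class Points per class.
#' @param sigma Marginal standard deviation.
#' @param d Centroid-to-boundary distance (default 1.7, the canonical
#'   geometry).
#' @param trials Monte Carlo trials (>= 100).
#' @param seed Optional integer seed.
#' @return Object of class `"accuracy_experiment"`: `samples`, `lo`,
#'   `median`, `hi` (95% band), `width`, `theoretical`, and the parameters.
#' @export
accuracy_experiment <- function(n_per_class = 59, sigma = 1.414, d = 1.7,
                                trials = 10000, seed = NULL) {
  if (trials < 100) abort("use at least 100 trials")
  if (!is.null(seed)) set.seed(seed)
  mus <- centroids_for_distance(d)
  acc <- vapply(seq_len(trials), function(i) {
    lda_trial_accuracy(n_per_class, sigma, mus[1, ], mus[2, ])
  }, 0)
  qs <- quantile(acc, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(samples = acc, lo = qs[1], median = qs[2], hi = qs[3],
                 width = qs[3] - qs[1],
                 theoretical = 1 - pwrong(d, sigma),
                 n_per_class = n_per_class, sigma = sigma, d = d,
                 trials = trials),
            class = "accuracy_experiment")
}

#' @export
print.accuracy_experiment <- function(x, ...) {
  cat(sprintf("LDA training accuracy over %d trials (n = %d/class, sigma = %.3f, d = %.2f)\n",
              x$trials, x$n_per_class, x$sigma, x$d))
  cat(sprintf("  95%% band (%.3f, %.3f), median %.3f, theoretical %.3f\n",
              x$lo, x$hi, x$median, x$theoretical))
  invisible(x)
}

#' Scaling of the accuracy confidence-interval width with sample size
#'
#' Runs [accuracy_experiment()] over a grid of `sigma` and `n` values at
#' fixed `d` and fits, per `sigma`, the one-parameter law
#' `width = a / sqrt(n)` by least squares.
#'
#' @param sigma_grid Marginal standard deviations (study range 0.707-2.83).
#' @param n_grid Per-class sample sizes (study range 10-500; at least 3
#'   values).
#' @param d Centroid-to-boundary distance.
#' @param trials Trials per grid cell.
#' @param seed Optional integer seed.
#' @return Object of class `"ci_width_scaling"`: `$grid` (sigma, n, width),
#'   `$fits` (sigma, a, rms_residual, relative_rms).
#' @export
ci_width_scaling <- function(sigma_grid = c(0.707, 1.414, 2.83),
                             n_grid = c(15, 30, 60, 120, 240),
                             d = 1.7, trials = 2000, seed = NULL) {
  if (length(n_grid) < 3) abort("need at least 3 sample sizes to fit the scaling")
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(sigma = sigma_grid, n = n_grid)
  grid$width <- purrr::map2_dbl(grid$sigma, grid$n, function(s, n) {
    accuracy_experiment(n, s, d = d, trials = trials)$width
  })
  fits <- grid |>
    dplyr::group_by(.data$sigma) |>
    dplyr::summarise(
      a = sum(.data$width / sqrt(.data$n)) / sum(1 / .data$n),
      rms_residual = sqrt(mean((.data$width - a / sqrt(.data$n))^2)),
      relative_rms = .data$rms_residual / mean(.data$width)
    )
  structure(list(grid = grid, fits = fits, d = d, trials = trials),
            class = "ci_width_scaling")
}

#' Lower accuracy bound as a function of separation and sample size
#'
#' For each combination of `d/sigma` ratio and per-class sample size, runs
#' the Monte Carlo accuracy experiment and reports the lower endpoint of the
#' 95% band -- the minimum training accuracy compatible (at 95% confidence)
#' with the drawn conditions. At `d/sigma = 1.96` the large-n asymptote is
#' accuracy 0.975, i.e. a 5% equivalent-randomness level.
#'
#' @param d_over_sigma Separation ratios (study range 0.5-2.5).
#' @param n_grid Per-class sample sizes (study range 10-2560).
#' @param trials Trials per cell.
#' @param seed Optional integer seed.
#' @return Tibble: `d_over_sigma`, `n`, `alb` (lower bound), `median`,
#'   `theoretical`.
#' @export
alb_curves <- function(d_over_sigma = c(0.5, 1.0, 1.5, 2.0, 2.5),
                       n_grid = c(10, 40, 160, 640, 2560),
                       trials = 10000, seed = NULL) {
  if (length(d_over_sigma) == 0 || length(n_grid) == 0) abort("grids must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(d_over_sigma = d_over_sigma, n = n_grid)
  res <- purrr::pmap_dfr(grid, function(d_over_sigma, n) {
    ex <- accuracy_experiment(n, sigma = 1, d = d_over_sigma, trials = trials)
    tibble::tibble(d_over_sigma = d_over_sigma, n = n, alb = ex$lo,
                   median = ex$median, theoretical = ex$theoretical)
  })
  res
}
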