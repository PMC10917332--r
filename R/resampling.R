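#' Bias-corrected and accelerated bootstrap interval
#'
#' BCa interval from a vector of bootstrap replicates. The bias correction
#' `z0` comes from the fraction of replicates below the plug-in estimate
#' `statistic(data)`; the acceleration `a` from the skewness of the jackknife
#' values of the statistic over the original records. When both are zero the
#' interval reduces to the percentile method.
#'
#' @param samples Numeric vector of bootstrap replicates (>= 100 for a stable
#'   interval; fewer is allowed but warned about).
#' @param statistic Function mapping a data subset to a scalar.
#' @param data The original data the bootstrap resampled: a vector, or a data
#'   frame resampled by rows.
#' @param level Coverage level (default 0.95).
#' @return Object of class `"bca_interval"`: `lo`, `hi`, `estimate`, `level`,
#'   `bias_correction` (z0), `acceleration` (a), `degenerate` flag.
#' @export
bca_interval <- function(samples, statistic, data, level = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) {
    warn("fewer than 100 bootstrap replicates; BCa endpoints will be noisy")
  }
  est <- if (is.data.frame(data)) statistic(data) else statistic(as.vector(data))
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  jack <- vapply(seq_len(n), function(i) {
    di <- if (is.data.frame(data)) data[-i, , drop = FALSE] else data[-i]
    statistic(di)
  }, 0)
  out <- bca_from_parts(samples, est, jack, level)
  structure(c(out, list(estimate = est, level = level)),
            class = "bca_interval")
}

# Core BCa arithmetic given the bootstrap replicates, the plug-in estimate
# and the jackknife values of the statistic.
bca_from_parts <- function(samples, est, jack, level) {
  if (diff(range(samples)) == 0) {
    return(list(lo = samples[1], hi = samples[1], bias_correction = 0,
                acceleration = 0, degenerate = TRUE))
  }
  frac <- mean(samples < est) + 0.5 * mean(samples == est)
  frac <- min(max(frac, 1 / (length(samples) + 1)),
              length(samples) / (length(samples) + 1))
  z0 <- qnorm(frac)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (!is.finite(den) || den == 0) 0 else num / den
  alpha <- (1 - level) / 2
  adj <- function(al) {
    z <- z0 + qnorm(al)
    pnorm(z0 + z / (1 - a * z))
  }
  qs <- quantile(samples, probs = c(adj(alpha), adj(1 - alpha)),
                 names = FALSE, type = 6)
  list(lo = qs[1], hi = qs[2], bias_correction = z0, acceleration = a,
       degenerate = FALSE)
}

#' @export
print.bca_interval <- function(x, ...) {
  cat(sprintf("BCa %.0f%% interval: (%.4g, %.4g), estimate %.4g (z0 = %.3f, a = %.4f)\n",
              100 * x$level, x$lo, x$hi, x$estimate,
              x$bias_correction, x$acceleration))
  invisible(x)
}

#' Taxon-resampling bootstrap of the phylogenetic discriminant
#'
#' Repeatedly resamples the training taxa with replacement (same size as the
#' original dataset), reruns the phylogenetic discriminant across the tree
#' ensemble for every resample, and collects the training metrics and test
#' posteriors of every individual run. A resample that collapses one class
#' below the fitting minimum is redrawn (and counted), so the number of
#' retained trials is exact. BCa intervals for the metric medians use, as
#' plug-in statistic, the per-metric median over the ensemble of a single
#' unresampled fit, with a leave-one-taxon-out jackknife for the
#' acceleration.
#'
#' @param train Partitioned specimen tibble from [partition_classes()].
#' @param trees Tree, list of trees, or [random_tree_ensemble()].
#' @param test Optional test records.
#' @param n_trials Bootstrap trials (study scale: 2000).
#' @param compute_intervals Compute BCa intervals (involves a jackknife over
#'   taxa); set `FALSE` when only the raw metric/posterior samples are
#'   needed.
#' @param lambda Fixed Pagel's lambda, or `NULL` to re-estimate per run.
#' @param threshold Posterior threshold for the class-2 tally.
#' @param seed Integer seed; the full run is reproducible from it.
#' @param level Coverage level for BCa intervals.
#' @return Object of class `"pfda_bootstrap"` with `$metrics` (one row per
#'   trial x tree), `$posteriors` (one row per trial x tree x test taxon),
#'   `$intervals` (BCa summaries), `$skipped` (redrawn degenerate trials).
#' @export
bootstrap_pfda <- function(train, trees, test = NULL, n_trials = 2000,
                           lambda = NULL, threshold = 0.5, seed = NULL,
                           level = 0.95, compute_intervals = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  trees <- as_tree_list(trees)
  n <- nrow(train)
  metrics <- vector("list", n_trials)
  posts <- vector("list", n_trials)
  skipped <- 0L
  for (b in seq_len(n_trials)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- train[idx, , drop = FALSE]
      if (sum(boot$class == 1L) >= 3 && sum(boot$class == 2L) >= 3 &&
          length(unique(boot$taxon_id[boot$class == 1L])) >= 2 &&
          length(unique(boot$taxon_id[boot$class == 2L])) >= 2) break
      skipped <- skipped + 1L
    }
    fit <- fit_pfda(boot, trees, test = test, lambda = lambda,
                    threshold = threshold)
    metrics[[b]] <- dplyr::mutate(fit$metrics, trial = b, .before = 1)
    if (!is.null(fit$posteriors)) {
      posts[[b]] <- dplyr::mutate(fit$posteriors, trial = b, .before = 1)
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  posteriors <- if (!is.null(test)) dplyr::bind_rows(posts) else NULL
  # plug-in statistic for BCa: per-metric median over the ensemble of a
  # single (unresampled) fit; jackknife leaves out one taxon at a time and
  # is shared across the four metrics
  metric_names <- c("accuracy", "balanced_accuracy", "mcc", "p_rand")
  intervals <- NULL
  if (compute_intervals) {
  fitstats <- function(d) {
    f <- fit_pfda(d, trees, test = NULL, lambda = lambda,
                  threshold = threshold)
    vapply(metric_names, function(m) median(f$metrics[[m]]), 0)
  }
  est <- fitstats(train)
  jack <- t(vapply(seq_len(n), function(i) fitstats(train[-i, , drop = FALSE]),
                   numeric(length(metric_names))))
  intervals <- purrr::map_dfr(metric_names, function(m) {
    ci <- bca_from_parts(metrics[[m]], est[[m]], jack[, m], level)
    tibble::tibble(metric = m, median = median(metrics[[m]]),
                   lo = ci$lo, hi = ci$hi,
                   bias_correction = ci$bias_correction,
                   acceleration = ci$acceleration)
  })
  }
  structure(list(metrics = metrics, posteriors = posteriors,
                 intervals = intervals, skipped = skipped,
                 n_trials = n_trials, trees_per_trial = length(trees),
                 threshold = threshold, level = level),
            class = "pfda_bootstrap")
}

#' @export
print.pfda_bootstrap <- function(x, ...) {
  cat(sprintf("pFDA bootstrap: %d trials x %d trees = %d runs (%d degenerate redraws)\n",
              x$n_trials, x$trees_per_trial, nrow(x$metrics), x$skipped))
  print(x$intervals)
  invisible(x)
}

#' Rank-permutation test for extinct/extant compactness disparity
#'
#' Tests whether one status group is displaced in the compactness ranking of
#' a class relative to the other. Two statistics are available. The default,
#' `"top_rank"`, is the joint depletion event on the minority group's two
#' best rank numbers: the p-value is the permutation probability that the
#' minority group's best rank is at least as large (i.e. as far from the top
#' of the ranking) as observed *and* its second-best rank likewise. This is
#' the convention that reproduces the published composition-test values
#' (0.0011 for the femoral diver class). `"rank_sum"` is the conventional
#' two-sided Mann-Whitney-type permutation test on the minority rank sum.
#' Both are rank-based and therefore invariant under monotone transforms of
#' the values.
#'
#' @param values Numeric vector (e.g. Cg), ranked in decreasing order
#'   internally (rank 1 = largest value).
#' @param labels Two-level grouping vector (e.g. extinct/extant).
#' @param n_perm Number of label permutations (study scale: 16e6; default
#'   1e5 for desk runs).
#' @param statistic `"top_rank"` or `"rank_sum"`.
#' @param seed Optional integer seed.
#' @return Object of class `"rank_permutation_test"`: `p`, `statistic`,
#'   `observed` (minority best ranks or rank sum), `minority`, `n_perm`.
#' @export
permutation_rank_test <- function(values, labels, n_perm = 1e5,
                                  statistic = c("top_rank", "rank_sum"),
                                  seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2) abort("labels must have exactly two levels")
  if (n_perm < 1e4) warn("fewer than 1e4 permutations; p-values will be coarse")
  minority <- names(tab)[which.min(tab)]
  m <- min(tab)
  n <- length(values)
  r <- rank(-values, ties.method = "average")   # rank 1 = largest value
  obs_ranks <- sort(r[labels == minority])
  if (statistic == "top_rank") {
    r1 <- obs_ranks[1]; r2 <- obs_ranks[2]
    if (m < 2) abort("top_rank statistic needs a minority group of size >= 2")
    b <- 0L
    for (i in seq_len(n_perm)) {
      pr <- sort.int(r[sample.int(n, m)], partial = 1:2)
      if (pr[1] >= r1 && pr[2] >= r2) b <- b + 1L
    }
    p <- (b + 1) / (n_perm + 1)
    observed <- c(first = r1, second = r2)
  } else {
    obs <- sum(obs_ranks)
    e <- m * (n + 1) / 2
    b <- 0L
    for (i in seq_len(n_perm)) {
      s <- sum(r[sample.int(n, m)])
      if (abs(s - e) >= abs(obs - e) - 1e-9) b <- b + 1L
    }
    p <- (b + 1) / (n_perm + 1)
    observed <- c(rank_sum = obs)
  }
  structure(list(p = p, statistic = statistic, observed = observed,
                 minority = minority, n_minority = m, n_total = n,
                 n_perm = n_perm),
            class = "rank_permutation_test")
}

#' @export
print.rank_permutation_test <- function(x, ...) {
  cat(sprintf("Rank permutation test (%s statistic), minority '%s' (%d of %d)\n",
              x$statistic, x$minority, x$n_minority, x$n_total))
  cat(sprintf("  observed: %s; p = %.4g (%d permutations)\n",
              paste(names(x$observed), x$observed, sep = " = ", collapse = ", "),
              x$p, x$n_perm))
  invisible(x)
}

#' Exact coin-flip point probability of a group split
#'
#' Probability, under fair coin flips, of observing exactly `k` members of
#' one status group among `n`: `choose(n, k) / 2^n`, computed in log space.
#' Symmetric in `k` and `n - k`; maximal at the balanced split. Summed over
#' `k = 0..n` it is exactly 1.
#'
#' @param k Minority (or either) group count, `0 <= k <= n`.
#' @param n Total count.
#' @return Point probability.
#' @export
coinflip_point_probability <- function(k, n) {
  if (any(k < 0) || any(k > n)) abort("k must lie in [0, n]")
  exp(lchoose(n, k) - n * log(2))
}
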