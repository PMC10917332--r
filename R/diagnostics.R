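#' Maximum-likelihood distribution fits with AICc comparison
#'
#' Fits a battery of candidate one-dimensional distributions to discriminant
#' scores by maximum likelihood and compares them with the small-sample
#' Akaike criterion. Candidates: `pooled_normal` (mean free, standard
#' deviation supplied externally -- the discriminant's own class model, whose
#' sd is pooled across both classes), `normal`, `uniform` (MLE = data range),
#' `weibull3` (three-parameter, location-shifted), `logistic`,
#' `mixture2_normal`, `mixture3_normal`, and `uniform_normal_mixture`.
#' Mixture weights count toward the parameter tally (`k = 3c - 1` for `c`
#' normal components). A candidate that fails to converge is flagged and the
#' others are still reported.
#'
#' Akaike weights are `exp(-dAICc / 2)`; `p_dist` renormalizes them to sum
#' to 1 over the fitted set.
#'
#' @param values Numeric vector of at least 20 scores.
#' @param families Character vector of candidate names (see above).
#' @param pooled_sd Standard deviation for the `pooled_normal` candidate;
#'   required if that family is requested.
#' @return Object of class `"dist_fit_comparison"`: a tibble with `family`,
#'   `k`, `loglik`, `aicc`, `delta_aicc`, `weight`, `p_dist`, `converged`,
#'   and a `params` list-column.
#' @export
fit_score_distributions <- function(values,
                                    families = c("normal", "uniform",
                                                 "weibull3", "logistic"),
                                    pooled_sd = NULL) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 20) abort("need at least 20 values to compare distribution fits")
  if (length(families) == 0) abort("candidate list is empty")
  if ("pooled_normal" %in% families && is.null(pooled_sd)) {
    abort("pooled_normal requires pooled_sd")
  }
  rows <- purrr::map(families, function(fam) {
    f <- tryCatch(fit_one_family(x, fam, pooled_sd),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$loglik)) {
      return(tibble::tibble(family = fam, k = NA_integer_,
                            loglik = NA_real_, aicc = NA_real_,
                            converged = FALSE, params = list(NULL)))
    }
    aicc <- -2 * f$loglik + 2 * f$k + 2 * f$k * (f$k + 1) / max(n - f$k - 1, 1)
    tibble::tibble(family = fam, k = f$k, loglik = f$loglik, aicc = aicc,
                   converged = TRUE, params = list(f$params))
  })
  out <- dplyr::bind_rows(rows)
  ok <- out$converged
  out$delta_aicc <- out$aicc - min(out$aicc[ok])
  out$weight <- exp(-out$delta_aicc / 2)
  out$p_dist <- out$weight / sum(out$weight[ok])
  out <- out[, c("family", "k", "loglik", "aicc", "delta_aicc",
                 "weight", "p_dist", "converged", "params")]
  structure(out, class = c("dist_fit_comparison", class(out)), n = n)
}

fit_one_family <- function(x, family, pooled_sd = NULL) {
  n <- length(x)
  switch(family,
    pooled_normal = {
      mu <- mean(x)
      ll <- sum(dnorm(x, mu, pooled_sd, log = TRUE))
      list(loglik = ll, k = 1L, params = c(mean = mu, sd = pooled_sd))
    },
    normal = {
      mu <- mean(x); s <- sqrt(mean((x - mu)^2))
      list(loglik = sum(dnorm(x, mu, s, log = TRUE)), k = 2L,
           params = c(mean = mu, sd = s))
    },
    uniform = {
      a <- min(x); b <- max(x)
      if (b <= a) abort("degenerate uniform fit")
      list(loglik = -n * log(b - a), k = 2L, params = c(min = a, max = b))
    },
    logistic = {
      nll <- function(p) -sum(dlogis(x, p[1], exp(p[2]), log = TRUE))
      o <- optim(c(mean(x), log(sd(x) * sqrt(3) / pi)), nll)
      list(loglik = -o$value, k = 2L,
           params = c(location = o$par[1], scale = exp(o$par[2])))
    },
    weibull3 = {
      # location-shifted Weibull; location profiled below min(x)
      nll <- function(p) {
        loc <- min(x) - exp(p[3])
        z <- x - loc
        -sum(stats::dweibull(z, exp(p[1]), exp(p[2]), log = TRUE))
      }
      o <- optim(c(log(1.5), log(sd(x) * 2), log(sd(x))), nll,
                 control = list(maxit = 2000))
      list(loglik = -o$value, k = 3L,
           params = c(shape = exp(o$par[1]), scale = exp(o$par[2]),
                      location = min(x) - exp(o$par[3])))
    },
    mixture2_normal = fit_normal_mixture(x, 2L),
    mixture3_normal = fit_normal_mixture(x, 3L),
    uniform_normal_mixture = fit_uniform_normal_mixture(x),
    abort(paste0("unknown candidate family: ", family))
  )
}

# Gaussian mixture by EM (mclust), unequal variances; k = 3c - 1.
fit_normal_mixture <- function(x, g) {
  fit <- suppressWarnings(
    Mclust(x, G = g, modelNames = "V", verbose = FALSE)
  )
  if (is.null(fit)) abort("mixture fit failed to converge")
  list(loglik = fit$loglik, k = 3L * g - 1L,
       params = c(weights = fit$parameters$pro,
                  means = fit$parameters$mean,
                  sds = sqrt(fit$parameters$variance$sigmasq)))
}

# Two-component mixture: uniform on a fitted interval + normal, by EM.
fit_uniform_normal_mixture <- function(x, max_iter = 200, tol = 1e-8) {
  a <- min(x); b <- max(x)
  w <- 0.5; mu <- mean(x); s <- sd(x) / 2
  du <- 1 / (b - a)
  ll_old <- -Inf
  for (i in seq_len(max_iter)) {
    pu <- w * du
    pn <- (1 - w) * dnorm(x, mu, s)
    gamma <- pu / (pu + pn)
    w <- mean(gamma)
    wn <- 1 - gamma
    mu <- sum(wn * x) / sum(wn)
    s <- sqrt(sum(wn * (x - mu)^2) / sum(wn))
    if (!is.finite(s) || s < 1e-8) abort("uniform+normal mixture degenerated")
    ll <- sum(log(w * du + (1 - w) * dnorm(x, mu, s)))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(loglik = ll, k = 5L,
       params = c(weight_uniform = w, min = a, max = b, mean = mu, sd = s))
}

#' Joint probability that both classes meet the discriminant's normal model
#'
#' The discriminant assumes both classes are normal with a pooled standard
#' deviation; the joint support for that assumption is the product of the
#' two classes' `p_dist` values for the pooled-normal candidate.
#'
#' @param fit1,fit2 [fit_score_distributions()] results for the two classes,
#'   each including the `pooled_normal` family.
#' @param family Family whose `p_dist` values are multiplied.
#' @return Scalar probability.
#' @export
joint_normality_probability <- function(fit1, fit2, family = "pooled_normal") {
  g <- function(f) {
    i <- which(f$family == family)
    if (length(i) != 1) abort(paste0("fit does not include family ", family))
    f$p_dist[i]
  }
  g(fit1) * g(fit2)
}

#' Variance-equivalence tests robust to non-normality
#'
#' Runs three classical two-group dispersion tests with the null of equal
#' variances: Brown-Forsythe (ANOVA on absolute deviations from group
#' medians), Levene (deviations from group means), and the Conover
#' squared-ranks test (normal approximation). All three are robust to
#' departures from normality.
#'
#' @param group1,group2 Numeric vectors, each of at least 5 values.
#' @return Tibble with `test`, `statistic`, `p`.
#' @export
variance_tests <- function(group1, group2) {
  x <- group1[is.finite(group1)]; y <- group2[is.finite(group2)]
  if (length(x) < 5 || length(y) < 5) abort("each group needs at least 5 values")
  if (sd(x) == 0 || sd(y) == 0) abort("degenerate group with zero variance")
  lev <- function(center) {
    d <- c(abs(x - center(x)), abs(y - center(y)))
    g <- factor(rep(1:2, c(length(x), length(y))))
    n <- length(d); k <- 2L
    dm <- tapply(d, g, mean); grand <- mean(d)
    ssb <- sum(tabulate(g) * (dm - grand)^2)
    ssw <- sum((d - dm[g])^2)
    stat <- (ssb / (k - 1)) / (ssw / (n - k))
    c(stat, pf(stat, k - 1, n - k, lower.tail = FALSE))
  }
  bf <- lev(median)
  lv <- lev(mean)
  # Conover squared-ranks: rank |x - group mean| over both groups, square,
  # sum in group 1, standardize.
  u <- c(abs(x - mean(x)), abs(y - mean(y)))
  r2 <- rank(u)^2
  n1 <- length(x); n <- length(u)
  t1 <- sum(r2[seq_len(n1)])
  rbar <- mean(r2)
  vr <- n1 * (n - n1) / (n * (n - 1)) * (sum(r2^2) - n * rbar^2)
  z <- (t1 - n1 * rbar) / sqrt(vr)
  tibble::tibble(
    test = c("brown_forsythe", "levene", "conover"),
    statistic = c(bf[1], lv[1], z),
    p = c(bf[2], lv[2], 2 * pnorm(-abs(z)))
  )
}

# One Hopkins trial: m sampled data points vs m uniform probes in the window.
# With torus = TRUE the window is treated as periodic (edge correction).
hopkins_trial <- function(pts, m, variant, window, hull = NULL,
                          torus = FALSE) {
  n <- nrow(pts)
  wx <- window[2] - window[1]; wy <- window[4] - window[3]
  nn_dist <- function(px, py, qx, qy) {
    dx <- abs(qx - px); dy <- abs(qy - py)
    if (torus) {
      dx <- pmin(dx, wx - dx)
      dy <- pmin(dy, wy - dy)
    }
    sqrt(min(dx^2 + dy^2))
  }
  samp <- sample.int(n, m)
  # nearest-neighbor distance from each sampled point to the rest of the data
  w <- vapply(samp, function(i) {
    nn_dist(pts[i, 1], pts[i, 2], pts[-i, 1], pts[-i, 2])
  }, 0)
  probes <- if (is.null(hull)) {
    cbind(runif(m, window[1], window[2]), runif(m, window[3], window[4]))
  } else {
    sample_in_hull(hull, m)
  }
  u <- vapply(seq_len(m), function(i) {
    nn_dist(probes[i, 1], probes[i, 2], pts[, 1], pts[, 2])
  }, 0)
  switch(variant,
    original = sum(u^2) / (sum(u^2) + sum(w^2)),  # exponent = dimension
    lj       = sum(u) / (sum(u) + sum(w)),        # unsquared distances
    fpm      = sum(u^2) / (sum(u^2) + sum(w^2))   # squared, hull window
  )
}

#' Hopkins clustering-tendency statistic
#'
#' Compares nearest-neighbor distances of randomly sampled data points with
#' those of uniform probe points; values near 0.5 indicate spatial
#' uniformity, values near 1 clustering. Variants: `"original"` (squared
#' distances, i.e. exponent = dimension, probes in the data's bounding box),
#' `"lj"` (Lawson-Jurs, unsquared distances), and `"fpm"` (Fernandez
#' Pierna-Massart, squared distances with probes drawn inside the data's
#' convex hull). The reported `H` is the mean over `reps` random trials,
#' each sampling `frac` of the points.
#'
#' Two p-values against the uniform null are reported, both upper-tail
#' (clustering inflates `H`): `p_beta` from the Beta(m, m) law of a single
#' trial (a heuristic when `reps > 1`), and `p_mc` from an empirical null of
#' `mc_trials` uniform point sets of the same size pushed through the
#' identical pipeline (this captures the finite-sample edge bias that pulls
#' `H` slightly below 0.5 in a bounding-box window).
#'
#' @param points Two-column matrix or data frame of coordinates (>= 15 rows).
#'   Whitened/transformed coordinates can be passed directly -- the statistic
#'   is representation-agnostic.
#' @param variant `"original"`, `"lj"`, or `"fpm"`.
#' @param frac Fraction of points sampled per trial (default 0.2).
#' @param reps Trials averaged into `H` (default 100).
#' @param mc_trials Uniform null sets for `p_mc` (study scale 10000; set 0
#'   to skip the Monte Carlo null).
#' @param window Sampling window `c(xmin, xmax, ymin, ymax)`; `NULL` uses
#'   the data's axis-aligned bounding box. Supplying the true support (when
#'   known, e.g. for generated data) removes the window-estimation bias.
#' @param edge_correction `"none"` or `"torus"` (treat the window as
#'   periodic when measuring distances -- the standard edge correction, under
#'   which the single-trial null law approaches Beta(m, m); requires an
#'   explicit `window` and applies to the box-window variants only).
#' @param seed Optional integer seed.
#' @return Object of class `"hopkins_result"`: `H`, `m`, `variant`,
#'   `p_beta`, `p_mc`, `reps`, `mc_trials`.
#' @export
hopkins_statistic <- function(points, variant = c("original", "lj", "fpm"),
                              frac = 0.2, reps = 100, mc_trials = 10000,
                              window = NULL, edge_correction = c("none", "torus"),
                              seed = NULL) {
  variant <- match.arg(variant)
  edge_correction <- match.arg(edge_correction)
  if (!is.null(seed)) set.seed(seed)
  pts <- as.matrix(points[, 1:2])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 15) abort("need at least 15 points")
  if (anyDuplicated(pts)) {
    warn("duplicate points jittered to keep nearest-neighbor distances positive")
    pts <- pts + matrix(rnorm(length(pts), 0, 1e-9 * max(apply(pts, 2, sd))),
                        ncol = 2)
  }
  torus <- edge_correction == "torus"
  if (torus && (is.null(window) || variant == "fpm")) {
    abort("torus edge correction needs an explicit box window")
  }
  m <- max(2L, round(frac * n))
  if (is.null(window)) window <- c(range(pts[, 1]), range(pts[, 2]))
  hull <- if (variant == "fpm") pts[grDevices::chull(pts), , drop = FALSE] else NULL
  H <- mean(vapply(seq_len(reps), function(i) {
    hopkins_trial(pts, m, variant, window, hull, torus)
  }, 0))
  p_beta <- pbeta(H, m, m, lower.tail = FALSE)
  p_mc <- NA_real_
  if (mc_trials > 0) {
    null_H <- vapply(seq_len(mc_trials), function(i) {
      up <- cbind(runif(n, window[1], window[2]), runif(n, window[3], window[4]))
      uw <- if (torus) window else c(range(up[, 1]), range(up[, 2]))
      uh <- if (variant == "fpm") up[grDevices::chull(up), , drop = FALSE] else NULL
      mean(vapply(seq_len(reps), function(j) {
        hopkins_trial(up, m, variant, uw, uh, torus)
      }, 0))
    }, 0)
    p_mc <- (sum(null_H >= H) + 1) / (mc_trials + 1)
  }
  structure(list(H = H, m = m, variant = variant, p_beta = p_beta,
                 p_mc = p_mc, reps = reps, mc_trials = mc_trials, n = n),
            class = "hopkins_result")
}

#' @export
print.hopkins_result <- function(x, ...) {
  cat(sprintf("Hopkins statistic (%s variant): H = %.3f (m = %d of %d, mean of %d trials)\n",
              x$variant, x$H, x$m, x$n, x$reps))
  cat(sprintf("  p (Beta null) = %.3g; p (Monte Carlo null) = %s\n",
              x$p_beta, ifelse(is.na(x$p_mc), "not run", sprintf("%.3g", x$p_mc))))
  invisible(x)
}

#' Kernel density and quantile-quantile summary against a reference family
#'
#' Plot-ready diagnostics for a score vector: a kernel density estimate over
#' a regular grid, and theoretical-versus-empirical quantile pairs against a
#' normal or uniform reference fitted by maximum likelihood. The signed
#' deviation pattern of the Q-Q points exposes systematic shape mismatches
#' (e.g. the S-shape of a uniform sample against a normal reference).
#'
#' @param values Numeric vector (>= 20 values, non-constant).
#' @param reference `"normal"` or `"uniform"`.
#' @param bw Kernel bandwidth passed to [stats::density()].
#' @return Object of class `"kde_qq_summary"`: `$kde` tibble (`x`,
#'   `density`), `$qq` tibble (`theoretical`, `empirical`, `deviation`),
#'   `max_abs_deviation`, and the fitted reference parameters.
#' @export
kde_qq_summary <- function(values, reference = c("normal", "uniform"),
                           bw = "nrd0") {
  reference <- match.arg(reference)
  x <- sort(values[is.finite(values)])
  if (length(x) < 20) abort("need at least 20 values")
  if (diff(range(x)) == 0) abort("degenerate constant values")
  kde <- density(x, bw = bw)
  pp <- ppoints(length(x))
  theo <- if (reference == "normal") {
    qnorm(pp, mean(x), sqrt(mean((x - mean(x))^2)))
  } else {
    qunif(pp, min(x), max(x))
  }
  dev <- x - theo
  structure(list(
    kde = tibble::tibble(x = kde$x, density = kde$y),
    qq = tibble::tibble(theoretical = theo, empirical = x, deviation = dev),
    max_abs_deviation = max(abs(dev)),
    reference = reference,
    params = if (reference == "normal") {
      c(mean = mean(x), sd = sqrt(mean((x - mean(x))^2)))
    } else c(min = min(x), max = max(x))
  ), class = "kde_qq_summary")
}
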