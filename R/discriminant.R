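#' Bivariate normal density
#'
#' Density of the two-dimensional Gaussian with centroid `mu` and covariance
#' `sigma`, the class model underlying the linear discriminant.
#'
#' @param p Numeric length-2 vector, or a 2-column matrix of points.
#' @param mu Length-2 centroid.
#' @param sigma 2x2 positive-definite covariance matrix.
#' @return Density value(s).
#' @export
bvn_density <- function(p, mu, sigma) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (!is.finite(det_s) || det_s <= 0) abort("sigma must be positive definite")
  md2 <- mahalanobis(p, center = mu, cov = sigma)
  exp(-md2 / 2) / (2 * pi * sqrt(det_s))
}

#' Theoretical misclassification probability of a linear boundary
#'
#' For a class drawn from an isotropic Gaussian with marginal standard
#' deviation `sigma` whose centroid sits at distance `d` from the decision
#' boundary, the mass on the wrong side is `0.5 * erfc(d / (sigma * sqrt(2)))`
#' (equivalently `pnorm(-d / sigma)`). This is the irreducible training
#' error of LDA in the large-sample limit: at `d = 1.96 sigma` it is 2.5%,
#' at `d = 2.33 sigma` it is 1%.
#'
#' @param d Distance from the class centroid to the boundary (>= 0).
#' @param sigma Marginal standard deviation (> 0).
#' @return Misclassification probability.
#' @export
pwrong <- function(d, sigma = 1) {
  if (any(d < 0)) abort("d must be non-negative")
  if (any(sigma <= 0)) abort("sigma must be positive")
  pnorm(-d / sigma)
}

#' Fit a two-class linear discriminant
#'
#' Classical LDA on points in the plane: class centroids are the class means,
#' the shared covariance is the unbiased pooled within-class estimator
#' (divisor `n - 2`), and a point is assigned to the class whose centroid is
#' nearer in the Mahalanobis metric. The decision boundary is the straight
#' line of equal Mahalanobis distance; with equal priors it is the
#' perpendicular bisector of the centroids in the whitened metric. Posterior
#' probabilities come from the Gaussian density ratio.
#'
#' @param data Data frame with numeric columns `x`, `y` and an integer/factor
#'   `class` column with exactly two levels coded 1 and 2.
#' @param priors Prior class probabilities, summing to 1 (default equal).
#' @return An object of class `"lda_fit"`: centroids, pooled covariance,
#'   boundary (point + direction), per-record discriminant scores and
#'   posterior probabilities of class 2.
#' @export
fit_lda <- function(data, priors = c(0.5, 0.5)) {
  if (!all(c("x", "y", "class") %in% names(data))) {
    abort("data must have columns x, y, class")
  }
  cls <- as.integer(as.character(data$class))
  if (!all(cls %in% c(1L, 2L))) abort("class labels must be 1 and 2")
  if (abs(sum(priors) - 1) > 1e-8 || any(priors <= 0)) {
    abort("priors must be positive and sum to 1")
  }
  X <- cbind(data$x, data$y)
  if (any(!is.finite(X))) abort("non-finite coordinates")
  n1 <- sum(cls == 1L); n2 <- sum(cls == 2L)
  if (n1 < 3 || n2 < 3) abort("each class needs at least 3 records")
  X1 <- X[cls == 1L, , drop = FALSE]; X2 <- X[cls == 2L, , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  if (sqrt(sum((mu1 - mu2)^2)) < 1e-12) {
    abort("degenerate fit: class centroids coincide")
  }
  S <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X2, 2, mu2))) / (n1 + n2 - 2)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det_s) || det_s <= 1e-14 * max(diag(S))^2) {
    abort("degenerate fit: pooled covariance is singular (collinear points)")
  }
  w <- solve(S, mu2 - mu1)               # discriminant direction
  mid <- (mu1 + mu2) / 2
  offset <- log(priors[2] / priors[1])
  fit <- structure(list(
    centroids = rbind(class1 = mu1, class2 = mu2),
    pooled_cov = S,
    priors = priors,
    n = c(n1 = n1, n2 = n2),
    direction = w,
    boundary = list(point = mid, direction = c(-w[2], w[1])),
    data = tibble::tibble(x = X[, 1], y = X[, 2], class = cls)
  ), class = "lda_fit")
  sc <- predict_lda_scores(fit, X)
  fit$data$score <- sc$score
  fit$data$p2 <- sc$p2
  fit$data$class_pred <- sc$class_pred
  fit
}

# Internal scorer shared by fit and predict.
predict_lda_scores <- function(fit, X) {
  w <- fit$direction
  mid <- fit$boundary$point
  score <- as.vector(X %*% w) - sum(mid * w)   # log density ratio class2/class1
  lp <- score + log(fit$priors[2] / fit$priors[1])
  p2 <- plogis(lp)
  tibble::tibble(score = score, p2 = p2,
                 class_pred = ifelse(lp > 0, 2L, 1L))
}

#' Predict class posteriors from a fitted discriminant
#'
#' @param object An `"lda_fit"`.
#' @param newdata Data frame with `x`, `y` columns (or a 2-column matrix).
#' @param ... Unused.
#' @return Tibble with `score` (signed log density ratio), `p2` (posterior
#'   probability of class 2) and `class_pred`.
#' @export
predict.lda_fit <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else cbind(newdata$x, newdata$y)
  predict_lda_scores(object, X)
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("Two-class linear discriminant fit\n")
  cat(sprintf("  n = %d + %d, priors = (%.2f, %.2f)\n",
              x$n[1], x$n[2], x$priors[1], x$priors[2]))
  cat(sprintf("  centroid 1: (%.3f, %.3f)  centroid 2: (%.3f, %.3f)\n",
              x$centroids[1, 1], x$centroids[1, 2],
              x$centroids[2, 1], x$centroids[2, 2]))
  acc <- mean(x$data$class_pred == x$data$class)
  cat(sprintf("  training accuracy: %.3f\n", acc))
  invisible(x)
}

#' Phylogenetic flexible discriminant analysis over a tree ensemble
#'
#' For each tree in the ensemble: scale the Brownian covariance by Pagel's
#' lambda (estimated from the training traits unless supplied), whiten
#' training and test records jointly with the inverse Cholesky factor
#' (intercept column included, so each record's generalized-least-squares
#' weight travels with it), fit the two-class flexible discriminant by
#' optimal scoring -- least-squares regression of the class indicator on the
#' whitened columns, followed by a one-dimensional Gaussian posterior on the
#' fitted discriminant scores -- and score the test records. The result is
#' one posterior probability of class 2 per tree per test taxon, per-tree
#' training metrics, and the per-record discriminant scores used by the
#' distributional diagnostics. With lambda forced to 0 on a star tree the
#' whitener is a multiple of the identity and the procedure reduces exactly
#' to ordinary LDA.
#'
#' @param train Partitioned specimen tibble from [partition_classes()].
#' @param trees A tree, list of trees, or [random_tree_ensemble()] output;
#'   tips must cover all training and test taxa.
#' @param test Optional specimen tibble of test records.
#' @param lambda `NULL` to re-estimate per tree, or a fixed value in `[0, 1]`.
#' @param threshold Posterior threshold used for the class-2 tally.
#' @param priors Class priors for the discriminant.
#' @return An object of class `"pfda_fit"` with `$posteriors` (tree, taxon,
#'   p2), `$metrics` (per-tree confusion-derived metrics), `$scores`
#'   (per-tree per-record discriminant values), `$lambda` (per tree), and
#'   `$threshold`. Summaries via [tidy.pfda_fit()].
#' @export
fit_pfda <- function(train, trees, test = NULL, lambda = NULL,
                     threshold = 0.5, priors = c(0.5, 0.5)) {
  trees <- as_tree_list(trees)
  train_pts <- as_points(train)
  test_pts <- if (!is.null(test) && nrow(test) > 0) as_points(test) else NULL
  taxa <- c(train_pts$taxon_id, if (!is.null(test_pts)) test_pts$taxon_id)
  post <- vector("list", length(trees))
  mets <- vector("list", length(trees))
  scs <- vector("list", length(trees))
  lam <- numeric(length(trees))
  for (k in seq_along(trees)) {
    r <- pfda_single_tree(train_pts, test_pts, trees[[k]], lambda, priors)
    lam[k] <- r$lambda
    mets[[k]] <- dplyr::mutate(r$metrics, tree = k, .before = 1)
    scs[[k]] <- dplyr::mutate(r$scores, tree = k, .before = 1)
    if (!is.null(r$posteriors)) {
      post[[k]] <- dplyr::mutate(r$posteriors, tree = k, .before = 1)
    }
  }
  structure(list(
    posteriors = if (!is.null(test_pts)) dplyr::bind_rows(post) else NULL,
    metrics = dplyr::bind_rows(mets),
    scores = dplyr::bind_rows(scs),
    lambda = lam,
    threshold = threshold,
    n_trees = length(trees),
    taxa = taxa
  ), class = "pfda_fit")
}

# Two-class flexible discriminant by optimal scoring: regress the centered
# class indicator on the whitened columns (whitened intercept included, no
# extra intercept), then put a one-dimensional two-Gaussian posterior on the
# fitted scores. Equivalent to LDA when the whitener is a multiple of the
# identity.
fda_optimal_scoring <- function(Mtrain, cls, Mtest = NULL, priors = c(0.5, 0.5)) {
  theta <- ifelse(cls == 2L, 1, -1)
  theta <- theta - mean(theta)
  beta <- tryCatch(qr.coef(qr(Mtrain), theta), error = function(e) {
    abort("degenerate discriminant design (collinear whitened columns)")
  })
  beta[is.na(beta)] <- 0
  s <- as.vector(Mtrain %*% beta)
  n1 <- sum(cls == 1L); n2 <- sum(cls == 2L)
  m1 <- mean(s[cls == 1L]); m2 <- mean(s[cls == 2L])
  if (!is.finite(m1) || !is.finite(m2) || abs(m2 - m1) < 1e-12) {
    abort("degenerate fit: class score means coincide")
  }
  v <- (sum((s[cls == 1L] - m1)^2) + sum((s[cls == 2L] - m2)^2)) / (n1 + n2 - 2)
  if (v <= 0) abort("degenerate fit: zero pooled score variance")
  post <- function(sc) {
    lp <- (m2 - m1) / v * (sc - (m1 + m2) / 2) + log(priors[2] / priors[1])
    plogis(lp)
  }
  list(beta = beta, scores = s, m1 = m1, m2 = m2, pooled_var = v,
       p2_train = post(s),
       p2_test = if (!is.null(Mtest)) post(as.vector(Mtest %*% beta)) else NULL,
       s_test = if (!is.null(Mtest)) as.vector(Mtest %*% beta) else NULL)
}

# One pFDA run on one tree. train/test already carry x, y columns.
pfda_single_tree <- function(train_pts, test_pts, tree, lambda, priors) {
  taxa <- c(train_pts$taxon_id, if (!is.null(test_pts)) test_pts$taxon_id)
  missing <- setdiff(unique(taxa), tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("taxa absent from tree: ", paste(head(missing, 5), collapse = ", ")))
  }
  drop <- setdiff(tree$tip.label, taxa)
  if (length(drop) > 0) tree <- ape::drop.tip(tree, drop)
  C_full <- bm_covariance(tree)
  # duplicated taxon rows (bootstrap resamples) index into the same tip
  idx <- match(taxa, rownames(C_full))
  C <- C_full[idx, idx, drop = FALSE]
  n_train <- nrow(train_pts)
  X <- cbind(1, c(train_pts$x, if (!is.null(test_pts)) test_pts$x),
             c(train_pts$y, if (!is.null(test_pts)) test_pts$y))
  lam <- if (is.null(lambda)) {
    optimize_lambda(X[seq_len(n_train), 2:3, drop = FALSE],
                    C[seq_len(n_train), seq_len(n_train), drop = FALSE])$lambda
  } else lambda
  Cl <- apply_lambda(C, lam)
  # duplicated tips make C(lambda) singular only at lambda = 1; nudge if so
  Xw <- tryCatch(whiten_traits(X, Cl), error = function(e) {
    whiten_traits(X, Cl + diag(1e-8 * mean(diag(Cl)), nrow(Cl)))
  })
  fda <- fda_optimal_scoring(Xw[seq_len(n_train), , drop = FALSE],
                             train_pts$class,
                             if (!is.null(test_pts)) {
                               Xw[-seq_len(n_train), , drop = FALSE]
                             },
                             priors = priors)
  pred <- ifelse(fda$p2_train >= 0.5, 2L, 1L)
  cm <- confusion_matrix(train_pts$class, pred)
  met <- classification_metrics(cm)
  scores <- tibble::tibble(taxon_id = train_pts$taxon_id,
                           class = train_pts$class, score = fda$scores,
                           p2 = fda$p2_train)
  posteriors <- NULL
  if (!is.null(test_pts)) {
    posteriors <- tibble::tibble(taxon_id = test_pts$taxon_id,
                                 p2 = fda$p2_test,
                                 class_pred = ifelse(fda$p2_test >= 0.5, 2L, 1L))
  }
  list(lambda = lam, metrics = met, posteriors = posteriors, scores = scores)
}

#' @export
print.pfda_fit <- function(x, ...) {
  cat(sprintf("pFDA fit over %d tree(s); lambda in [%.3f, %.3f]\n",
              x$n_trees, min(x$lambda), max(x$lambda)))
  cat(sprintf("  median training accuracy: %.3f\n", median(x$metrics$accuracy)))
  if (!is.null(x$posteriors)) {
    cat(sprintf("  %d test taxa scored per tree\n",
                length(unique(x$posteriors$taxon_id))))
  }
  invisible(x)
}
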