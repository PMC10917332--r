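#' Brownian-motion covariance of a phylogenetic tree
#'
#' Under Brownian trait evolution the covariance between two tips equals the
#' shared root-to-tip path length (the depth of their most recent common
#' ancestor); the diagonal holds each tip's root-to-tip length.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric positive-semidefinite matrix, rows/columns named by tip.
#' @export
bm_covariance <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("tree has negative branch lengths")
  ape::vcv.phylo(tree)
}

#' Scale a phylogenetic covariance by Pagel's lambda
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` is the full Brownian structure; `lambda = 0`
#' removes all phylogenetic correlation (star-tree limit).
#'
#' @param C Covariance matrix from [bm_covariance()].
#' @param lambda Signal strength in `[0, 1]`.
#' @return The rescaled covariance matrix.
#' @export
apply_lambda <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("lambda must be a single value in [0, 1]")
  }
  D <- diag(C)
  C <- C * lambda
  diag(C) <- D
  C
}

# Inverse lower-Cholesky factor of C: W such that W C t(W) = I.
whitening_factor <- function(C) {
  R <- tryCatch(chol(C), error = function(e) {
    abort(paste0("phylogenetic covariance is not positive definite (",
                 conditionMessage(e), "); check for zero-length or duplicated tips"))
  })
  # C = t(R) %*% R, so W = solve(t(R)) and W C W' = I
  backsolve(R, diag(nrow(C)), transpose = TRUE)
}

#' Whiten a trait matrix against a phylogenetic covariance
#'
#' Applies the generalized-least-squares decorrelation `W X`, where `W` is the
#' inverse lower Cholesky factor of `C`, so that Brownian-correlated rows
#' become independent. Row order of `X` must match the row order of `C`.
#'
#' @param X Numeric matrix (tips by variables, typically with an intercept
#'   column) or a vector.
#' @param C Phylogenetic covariance (after any lambda scaling).
#' @return The transformed matrix `W X`.
#' @export
whiten_traits <- function(X, C) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(C)) abort("row count of X must match dimension of C")
  R <- tryCatch(chol(C), error = function(e) {
    abort("phylogenetic covariance is not positive definite; cannot whiten")
  })
  backsolve(R, X, transpose = TRUE)
}

# Profile log-likelihood of columns of X under BM with covariance sigma2 * C,
# each column with its own GLS mean and variance.
bm_profile_loglik <- function(X, C) {
  X <- as.matrix(X)
  n <- nrow(X)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  Xw <- backsolve(R, X, transpose = TRUE)
  onew <- backsolve(R, rep(1, n), transpose = TRUE)
  ll <- 0
  for (j in seq_len(ncol(X))) {
    mu <- sum(onew * Xw[, j]) / sum(onew^2)
    rss <- sum((Xw[, j] - mu * onew)^2)
    s2 <- rss / n
    if (s2 <= 0) return(-Inf)
    ll <- ll + (-n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2)
  }
  ll
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles the Brownian-motion likelihood of the trait matrix over the
#' lambda-scaled covariance `C(lambda)` with a coarse grid on `[0, 1]`
#' followed by local refinement, each column of `X` getting its own GLS mean
#' and rate.
#'
#' @param X Trait matrix or vector (tips by variables), rows ordered as `C`.
#' @param C Brownian covariance from [bm_covariance()] (lambda = 1).
#' @param grid_step Grid resolution of the initial search.
#' @return List with `lambda` (the estimate) and `loglik`.
#' @export
optimize_lambda <- function(X, C, grid_step = 0.01) {
  X <- as.matrix(X)
  if (nrow(X) < 10) abort("lambda optimization needs at least 10 tips")
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(l) bm_profile_loglik(X, apply_lambda(C, l)), 0)
  if (all(!is.finite(ll))) abort("likelihood is degenerate for every lambda")
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- tryCatch(
    optimize(function(l) bm_profile_loglik(X, apply_lambda(C, l)),
             interval = c(lo, hi), maximum = TRUE),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    warn("local refinement failed; returning grid maximum")
    return(list(lambda = grid[i], loglik = ll[i]))
  }
  if (opt$objective >= ll[i]) {
    list(lambda = opt$maximum, loglik = opt$objective)
  } else {
    list(lambda = grid[i], loglik = ll[i])
  }
}

#' Random branch-length tree ensemble
#'
#' Generates an ensemble of trees sharing one topology, with every branch
#' length independently multiplied by a uniform factor. This emulates the
#' informal-supertree scheme of repeating an analysis across many trees with
#' varying branch lengths to absorb stratigraphic (branch-length)
#' uncertainty.
#'
#' @param tree Template [ape::phylo] tree with branch lengths.
#' @param n Number of trees (default 100).
#' @param seed Integer seed; the ensemble is fully reproducible from it.
#' @param factor_range Range of the uniform branch-length multiplier.
#' @return A list of `n` trees with class `"tree_ensemble"`.
#' @export
random_tree_ensemble <- function(tree, n = 100, seed = NULL,
                                 factor_range = c(0.5, 1.5)) {
  if (!is.numeric(n) || n < 1) abort("n must be a positive count")
  if (any(factor_range <= 0)) abort("branch-length factors must be positive")
  if (!is.null(seed)) set.seed(seed)
  trees <- lapply(seq_len(n), function(i) {
    t2 <- tree
    t2$edge.length <- tree$edge.length *
      runif(length(tree$edge.length), factor_range[1], factor_range[2])
    t2
  })
  structure(trees, class = c("tree_ensemble", "list"), seed = seed)
}

# Coerce a single tree or ensemble to a plain list of trees.
as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "tree_ensemble") || (is.list(trees) &&
      all(vapply(trees, inherits, TRUE, "phylo")))) {
    return(unclass(trees))
  }
  abort("expected a phylo tree, a list of trees, or a tree_ensemble")
}
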