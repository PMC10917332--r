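#' Two-class isotropic Gaussian point clouds
#'
#' Draws `n` points per class from bivariate normals with covariance
#' `sigma^2 I` and centroids at distance `d` from the `y = x` decision
#' boundary (defaults: the canonical geometry with centroids `(1.2, -1.2)`
#' and `(-1.2, 1.2)`, i.e. `d = 1.7`).
#'
#' @param n Points per class.
#' @param sigma Marginal standard deviation.
#' @param d Centroid-to-boundary distance.
#' @param seed Optional integer seed.
#' @return Tibble with `x`, `y`, `class` (1/2).
#' @export
sim_two_class <- function(n, sigma = 0.55, d = 1.7, seed = NULL) {
  if (n < 1) abort("n must be positive")
  if (sigma <= 0) abort("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  mus <- centroids_for_distance(d)
  tibble::tibble(
    x = c(rnorm(n, mus[1, 1], sigma), rnorm(n, mus[2, 1], sigma)),
    y = c(rnorm(n, mus[1, 2], sigma), rnorm(n, mus[2, 2], sigma)),
    class = rep(1:2, each = n)
  )
}

# Point-in-convex-polygon test; hull vertices in chull order.
in_hull <- function(px, py, hull) {
  nh <- nrow(hull)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cross <- (hull[j, 1] - hull[i, 1]) * (py - hull[i, 2]) -
             (hull[j, 2] - hull[i, 2]) * (px - hull[i, 1])
    inside <- inside & (cross <= 1e-12 * max(abs(hull)))
  }
  inside
}

# Rejection-sample m uniform points inside a convex hull (vertex matrix in
# chull order, which is clockwise, hence the <= test in in_hull).
sample_in_hull <- function(hull, m) {
  xr <- range(hull[, 1]); yr <- range(hull[, 2])
  out <- matrix(0, 0, 2)
  while (nrow(out) < m) {
    k <- max(2 * (m - nrow(out)), 16)
    px <- runif(k, xr[1], xr[2]); py <- runif(k, yr[1], yr[2])
    ok <- in_hull(px, py, hull)
    out <- rbind(out, cbind(px[ok], py[ok]))
  }
  out[seq_len(m), , drop = FALSE]
}

#' Uniform random points clipped to a template's convex hull
#'
#' Rejection-samples points uniformly inside the convex hull of a template
#' point set -- the null configuration against which clustering tendency is
#' judged.
#'
#' @param template Two-column matrix/data frame of at least 3 non-collinear
#'   points.
#' @param n Number of points to draw.
#' @param seed Optional integer seed.
#' @return Tibble with `x`, `y`.
#' @export
sim_uniform_hull <- function(template, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- as.matrix(template[, 1:2])
  hull_idx <- grDevices::chull(pts)
  if (length(hull_idx) < 3) abort("template hull is degenerate")
  hull <- pts[hull_idx, , drop = FALSE]
  if (n == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  s <- sample_in_hull(hull, n)
  tibble::tibble(x = s[, 1], y = s[, 2])
}

#' Random tree with Brownian-motion traits at a given Pagel's lambda
#'
#' Simulates a pure-birth tree and draws trait columns from a multivariate
#' normal with covariance `rate * C(lambda)`, where `C` is the Brownian
#' covariance of the tree. Used for parameter-recovery checks of the lambda
#' estimator and for exercising the whitening step.
#'
#' @param n_tips Number of tips (>= 10).
#' @param lambda Pagel's lambda of the generating covariance.
#' @param rate Brownian rate (variance multiplier).
#' @param n_traits Number of independent trait columns.
#' @param seed Optional integer seed.
#' @return List with `tree` (phylo) and `traits` (tips x traits matrix,
#'   rows named by tip, in `tree$tip.label` order).
#' @export
sim_bm_dataset <- function(n_tips, lambda = 1, rate = 1, n_traits = 1,
                           seed = NULL) {
  if (n_tips < 10) abort("n_tips must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  C <- apply_lambda(bm_covariance(tree), lambda)
  L <- t(chol(rate * C))
  Z <- matrix(rnorm(n_tips * n_traits), n_tips, n_traits)
  traits <- L %*% Z
  rownames(traits) <- rownames(C)
  traits <- traits[tree$tip.label, , drop = FALSE]
  list(tree = tree, traits = traits)
}

#' Specimen table with a controllable extinct/extant compactness shift
#'
#' Emulates a class whose extinct and extant members are drawn from
#' different compactness distributions. Extant Cg follows a Beta
#' distribution (respecting the (0, 1] support of compactness); extinct Cg
#' is shifted upward by `delta` and clipped into (0, 1]. Diameters are
#' log-normal around a typical small-amniote bone.
#'
#' @param n_extinct,n_extant Group sizes (>= 2 each).
#' @param delta Upward Cg shift of the extinct group (>= 0).
#' @param shape1,shape2 Beta parameters of the extant base distribution
#'   (defaults give mean 0.75, roughly the diver-class level).
#' @param seed Optional integer seed.
#' @return Specimen tibble with `status` filled in.
#' @export
sim_status_shift <- function(n_extinct, n_extant, delta = 0,
                             shape1 = 6, shape2 = 2, seed = NULL) {
  if (n_extinct < 2 || n_extant < 2) abort("group sizes must be at least 2")
  if (delta < 0) abort("delta must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- n_extinct + n_extant
  cg <- rbeta(n, shape1, shape2)
  cg[seq_len(n_extinct)] <- pmin(cg[seq_len(n_extinct)] + delta, 1)
  cg <- pmax(cg, 1e-6)
  tibble::tibble(
    taxon_id = sprintf("taxon_%03d", seq_len(n)),
    md_mm = exp(rnorm(n, log(15), 0.8)),
    cg = cg,
    fly_code = "0",
    dive_code = "2",
    status = rep(c("extinct", "extant"), c(n_extinct, n_extant)),
    role = "train"
  )
}

#' Synthetic terrestrial (F0D0) femoral class
#'
#' A labelled-synthetic stand-in for the terrestrial femoral training class,
#' whose raw records are not published. It reproduces the published summary
#' features of that class: 59 records, mean compactness 0.610 with a uniform
#' spread (uniformity being the best-supported distribution for this class),
#' and log10-diameter uniform with its median at the published 11.5 mm.
#'
#' @param n Number of records.
#' @param seed Optional integer seed.
#' @return Specimen tibble coded `F0D0`.
#' @export
synthetic_terrestrial_class <- function(n = 59, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    taxon_id = sprintf("synthetic_terrestrial_%02d", seq_len(n)),
    md_mm = 10^runif(n, 0, 2 * log10(11.5)),
    cg = runif(n, 0.225, 0.995),
    fly_code = "0",
    dive_code = "0",
    status = "unknown",
    role = "train"
  )
}

#' Synthetic full femoral training dataset
#'
#' Combines the published femoral diver class ([femoral_diver_records()])
#' with the labelled-synthetic terrestrial class
#' ([synthetic_terrestrial_class()]) into a two-class training table, for
#' pipeline runs that need a complete femoral dataset.
#'
#' @param seed Optional integer seed (drives the synthetic class).
#' @return Specimen tibble with both classes.
#' @export
synthetic_femoral_dataset <- function(seed = NULL) {
  divers <- femoral_diver_records()
  divers$rank <- NULL
  dplyr::bind_rows(divers, synthetic_terrestrial_class(seed = seed))
}
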