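test_that("bivariate density matches closed-form anchors", {
  expect_equal(bvn_density(c(0, 0), c(0, 0), diag(2)), 1 / (2 * pi),
               tolerance = 1e-12)
  # equal Mahalanobis distance from two centroids gives equal densities:
  # the boundary through the origin is orthogonal to solve(sigma, mu2 - mu1)
  sigma <- matrix(c(1, 0.3, 0.3, 2), 2)
  mu1 <- c(1, -1); mu2 <- c(-1, 1)
  w <- solve(sigma, mu2 - mu1)
  p <- 0.8 * c(-w[2], w[1])
  expect_equal(bvn_density(p, mu1, sigma), bvn_density(p, mu2, sigma),
               tolerance = 1e-12)
  # total mass 1 by grid quadrature
  g <- seq(-6, 6, by = 0.05)
  grid <- as.matrix(expand.grid(x = g, y = g))
  mass <- sum(bvn_density(grid, c(0.3, -0.2),
                          matrix(c(1.2, 0.4, 0.4, 0.8), 2))) * 0.05^2
  expect_equal(mass, 1, tolerance = 1e-3)
  expect_error(bvn_density(c(0, 0), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("theoretical misclassification matches its anchor values", {
  expect_equal(pwrong(1.96), 0.025, tolerance = 1e-3)
  expect_equal(pwrong(2.33), 0.01, tolerance = 0.015)
  expect_equal(pwrong(1.7, 1.414), 0.115, tolerance = 5e-3)
  expect_equal(pwrong(0, 2), 0.5)
  expect_error(pwrong(-1), "non-negative")
})

test_that("the symmetric geometry yields the y = x boundary", {
  pts <- toy_points(n = 4000, sigma = 0.55, seed = 9)
  fit <- fit_lda(pts)
  b <- fit$boundary
  slope <- b$direction[2] / b$direction[1]
  intercept <- b$point[2] - slope * b$point[1]
  expect_equal(slope, 1, tolerance = 0.05)
  expect_equal(intercept, 0, tolerance = 0.05)
})

test_that("classification agrees with a brute-force Mahalanobis oracle", {
  for (s in 1:8) {
    pts <- toy_points(n = 5, sigma = 1, seed = 100 + s)  # 10-point instances
    fit <- fit_lda(pts)
    X <- cbind(pts$x, pts$y)
    expect_identical(fit$data$class_pred, mahalanobis_oracle(fit, X))
  }
})

test_that("posteriors match an independent reference implementation", {
  skip_if_not_installed("MASS")
  pts <- toy_points(n = 40, sigma = 1.2, seed = 12)
  fit <- fit_lda(pts)
  ref <- MASS::lda(class ~ x + y, data = pts, prior = c(0.5, 0.5))
  ref_post <- stats::predict(ref, pts)$posterior[, "2"]
  expect_equal(fit$data$p2, unname(ref_post), tolerance = 0.02)
  expect_equal(fit$data$class_pred,
               as.integer(as.character(stats::predict(ref, pts)$class)))
})

test_that("degenerate configurations are rejected", {
  pts <- toy_points(n = 10, seed = 3)
  # identical centroids: class 2 is a relabeled copy of class 1
  dup <- pts
  dup$x <- rep(pts$x[pts$class == 1], 2)
  dup$y <- rep(pts$y[pts$class == 1], 2)
  expect_error(fit_lda(dup), "centroids coincide")
  # collinear points give a singular pooled covariance
  line <- tibble::tibble(x = c(1:4, 6:9), y = c(1:4, 6:9) * 2,
                         class = rep(1:2, each = 4))
  expect_error(fit_lda(line), "singular|degenerate")
  # tiny classes
  expect_error(fit_lda(pts[c(1, 2, 11, 12), ]), "at least 3")
})

test_that("posteriors are monotone along the inter-centroid axis", {
  pts <- toy_points(n = 50, sigma = 1, seed = 21)
  fit <- fit_lda(pts)
  mu1 <- fit$centroids[1, ]; mu2 <- fit$centroids[2, ]
  tt <- seq(-0.5, 1.5, length.out = 41)
  path <- cbind(mu1[1] + tt * (mu2[1] - mu1[1]),
                mu1[2] + tt * (mu2[2] - mu1[2]))
  p2 <- predict(fit, path)$p2
  expect_true(all(diff(p2) >= -1e-12))
})

test_that("the boundary is invariant under common affine rescaling", {
  pts <- toy_points(n = 60, sigma = 1, seed = 30)
  fit1 <- fit_lda(pts)
  scaled <- dplyr::mutate(pts, x = 3 * x + 2, y = 0.5 * y - 1)
  fit2 <- fit_lda(scaled)
  # classifications (and posteriors) are unchanged by the affine map
  expect_identical(fit1$data$class_pred, fit2$data$class_pred)
  expect_equal(fit1$data$p2, fit2$data$p2, tolerance = 1e-9)
})

test_that("empirical training error converges to the theoretical rate", {
  pts <- toy_points(n = 5000, sigma = 1.414, seed = 40)
  fit <- fit_lda(pts)
  err <- mean(fit$data$class_pred != fit$data$class)
  expect_lt(abs(err - pwrong(1.7, 1.414)), 0.01)
  expect_gt(err, 0)  # classification is never error-free at finite d/sigma
})

test_that("pFDA with a star tree at lambda 0 reproduces plain LDA", {
  ds <- toy_dataset(n1 = 8, n2 = 8, seed = 17)
  part <- partition_classes(ds, "F0D0_vs_F0D2")
  test <- tibble::tibble(taxon_id = "probe", md_mm = 30, cg = 0.9,
                         fly_code = "0", dive_code = "unknown",
                         status = "unknown", role = "test")
  tr <- star_tree(c(part$taxon_id, "probe"))
  pf <- fit_pfda(part, tr, test = test, lambda = 0)
  lda <- fit_lda(dplyr::select(as_points(part), x, y, class))
  expect_equal(sort(pf$scores$p2), sort(lda$data$p2), tolerance = 1e-8)
  expect_equal(pf$posteriors$p2, predict(lda, as_points(test))$p2,
               tolerance = 1e-8)
})

test_that("pFDA returns one posterior per tree and a confident centroid probe", {
  ds <- toy_dataset(n1 = 10, n2 = 10, seed = 23)
  # widen separation: classes already split in cg; shrink within-class noise
  part <- partition_classes(ds, "F0D0_vs_F0D2")
  centroid2 <- tibble::tibble(
    taxon_id = "at_centroid",
    md_mm = 10^mean(log10(part$md_mm[part$class == 2])),
    cg = mean(part$cg[part$class == 2]),
    fly_code = "0", dive_code = "unknown", status = "unknown", role = "test")
  ens <- random_tree_ensemble(star_tree(c(part$taxon_id, "at_centroid")),
                              n = 12, seed = 5)
  pf <- fit_pfda(part, ens, test = centroid2, lambda = 0.05)
  expect_equal(nrow(pf$posteriors), 12)
  expect_equal(tidy(pf)$n_trees, 12)
  # density-ratio oracle: a point at the class-2 centroid of well-separated
  # classes is confidently class 2
  expect_gt(tidy(pf)$median_p2, 0.99)
  # missing taxon is reported by name
  bad_tree <- star_tree(part$taxon_id)
  expect_error(fit_pfda(part, bad_tree, test = centroid2), "at_centroid")
})
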