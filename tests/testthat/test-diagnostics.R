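test_that("distribution comparison recovers the generating family", {
  set.seed(101)
  fams <- c("normal", "uniform", "logistic", "weibull3")
  # uniform draws: the uniform family wins decisively
  u <- runif(59, -2, 1)
  fu <- fit_score_distributions(u, fams)
  expect_equal(fu$family[fu$delta_aicc == 0], "uniform")

  # normal draws: a normal-type family carries the weight in most replicates
  wins <- vapply(1:20, function(i) {
    x <- rnorm(59)
    f <- fit_score_distributions(x, fams)
    f$family[which.min(f$aicc)] %in% c("normal", "logistic", "weibull3")
  }, TRUE)
  expect_gte(mean(wins), 0.9)

  # structural identities of the comparison table
  expect_equal(min(fu$delta_aicc, na.rm = TRUE), 0)
  expect_equal(fu$weight, exp(-fu$delta_aicc / 2))
  expect_equal(sum(fu$p_dist, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_error(fit_score_distributions(rnorm(10), fams), "at least 20")
})

test_that("adding a strictly worse candidate leaves the winner unchanged", {
  set.seed(55)
  x <- runif(80, -1, 3)
  small <- fit_score_distributions(x, c("normal", "uniform"))
  big <- fit_score_distributions(x, c("normal", "uniform", "logistic"),
                                 pooled_sd = NULL)
  expect_identical(small$family[small$delta_aicc == 0],
                   big$family[big$delta_aicc == 0])
})

test_that("mixture candidates fit and the pooled-normal uses the given sd", {
  set.seed(61)
  x <- c(rnorm(40, -1, 0.4), rnorm(40, 1.5, 0.5))
  f <- fit_score_distributions(x, c("normal", "mixture2_normal"),
                               pooled_sd = NULL)
  expect_true(all(f$converged))
  expect_equal(f$family[f$delta_aicc == 0], "mixture2_normal")

  fp <- fit_score_distributions(rnorm(50), c("pooled_normal", "normal"),
                                pooled_sd = 2)
  p <- fp$params[[which(fp$family == "pooled_normal")]]
  expect_equal(unname(p["sd"]), 2)
  expect_equal(fp$k[fp$family == "pooled_normal"], 1L)
  expect_error(fit_score_distributions(rnorm(50), "pooled_normal"),
               "pooled_sd")
})

test_that("joint normality probability multiplies the class p_dist values", {
  set.seed(71)
  f1 <- fit_score_distributions(rnorm(60), c("pooled_normal", "uniform"),
                                pooled_sd = 1)
  f2 <- fit_score_distributions(rnorm(60, 2), c("pooled_normal", "uniform"),
                                pooled_sd = 1)
  jp <- joint_normality_probability(f1, f2)
  expect_equal(jp,
               f1$p_dist[f1$family == "pooled_normal"] *
                 f2$p_dist[f2$family == "pooled_normal"])
  expect_lte(jp, 1)
  expect_error(joint_normality_probability(f1, f2, family = "weibull3"),
               "does not include")
})

test_that("variance tests hold their size and detect scale differences", {
  set.seed(81)
  # type-I: equal variances rejected at roughly the nominal rate
  rej <- matrix(NA, 150, 3)
  for (i in 1:150) {
    vt <- variance_tests(rnorm(60), rnorm(60))
    rej[i, ] <- vt$p < 0.05
  }
  expect_true(all(colMeans(rej) < 0.12))

  # power: a doubled scale is caught most of the time
  pw <- matrix(NA, 40, 3)
  for (i in 1:40) {
    vt <- variance_tests(rnorm(60), rnorm(60, 0, 2))
    pw[i, ] <- vt$p < 0.05
  }
  expect_true(all(colMeans(pw) >= 0.8))
  expect_error(variance_tests(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("Brown-Forsythe and Levene match the reference implementation", {
  skip_if_not_installed("car")
  set.seed(91)
  x <- rnorm(40); y <- rnorm(35, 0, 1.6)
  vt <- variance_tests(x, y)
  g <- factor(rep(1:2, c(40, 35)))
  ref_bf <- car::leveneTest(c(x, y), g, center = median)
  ref_lv <- car::leveneTest(c(x, y), g, center = mean)
  expect_equal(vt$statistic[vt$test == "brown_forsythe"],
               ref_bf$`F value`[1], tolerance = 1e-10)
  expect_equal(vt$p[vt$test == "brown_forsythe"],
               ref_bf$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(vt$statistic[vt$test == "levene"],
               ref_lv$`F value`[1], tolerance = 1e-10)
})

test_that("Hopkins statistic separates uniform from clustered point sets", {
  set.seed(111)
  # uniform: H near 0.5, null not rejected
  unif <- cbind(runif(80), runif(80))
  h <- hopkins_statistic(unif, "original", reps = 60, mc_trials = 400, seed = 1)
  expect_lt(abs(h$H - 0.5), 0.08)
  expect_gt(h$p_mc, 0.05)

  # two tight separated blobs: clustered, strongly rejected
  blobs <- rbind(cbind(rnorm(40, 0, 0.02), rnorm(40, 0, 0.02)),
                 cbind(rnorm(40, 1, 0.02), rnorm(40, 1, 0.02)))
  hc <- hopkins_statistic(blobs, "original", reps = 60, mc_trials = 400,
                          seed = 2)
  expect_gt(hc$H, 0.8)
  expect_lt(hc$p_mc, 0.01)

  # all three variants run and stay in (0, 1); transformed coordinates pass
  # through unchanged in interface terms
  wpts <- whiten_traits(unif, diag(80) * 2)
  for (v in c("original", "lj", "fpm")) {
    hv <- hopkins_statistic(wpts, v, reps = 20, mc_trials = 0, seed = 3)
    expect_gt(hv$H, 0); expect_lt(hv$H, 1)
  }
  expect_error(hopkins_statistic(unif[1:10, ]), "at least 15")
})

test_that("kde/qq summary flags shape mismatches against the reference", {
  set.seed(121)
  # normal sample vs normal reference: deviations inside a KS-style envelope
  x <- rnorm(200)
  s <- kde_qq_summary(x, "normal")
  expect_lt(s$max_abs_deviation, 1)
  expect_equal(nrow(s$qq), 200)

  # uniform sample vs normal reference: systematic S-shape, i.e. the sign of
  # the deviation flips from the tails to the center
  u <- runif(200)
  su <- kde_qq_summary(u, "normal")
  dev <- su$qq$deviation
  expect_gt(mean(dev[1:10] > 0), 0.8)      # lower tail above the line
  expect_lt(mean(dev[191:200] > 0), 0.2)   # upper tail below the line
  expect_error(kde_qq_summary(rep(1, 30)), "degenerate")
})
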