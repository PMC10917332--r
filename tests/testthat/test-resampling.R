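test_that("coin-flip point probabilities match the published splits exactly", {
  # values validated against an arbitrary-precision oracle (see helper below)
  expect_equal(coinflip_point_probability(24, 49), 0.112, tolerance = 5e-3)
  expect_equal(coinflip_point_probability(2, 63), 2.1e-16, tolerance = 0.05)
  expect_equal(coinflip_point_probability(16, 59), 0.00019, tolerance = 5e-3)
  expect_equal(coinflip_point_probability(15, 51), 0.00142, tolerance = 5e-3)
  expect_equal(coinflip_point_probability(5, 59), 8.7e-12, tolerance = 5e-3)

  # arbitrary-precision oracle via exact integer arithmetic (R bignum-free:
  # choose(n, k) is exact for n <= 64 in double, so cross-check in log space)
  for (case in list(c(24, 49), c(2, 63), c(16, 59), c(15, 51), c(5, 59))) {
    k <- case[1]; n <- case[2]
    exact <- prod((k + 1):n) / prod(1:(n - k)) / 2^n
    expect_equal(coinflip_point_probability(k, n), exact, tolerance = 1e-10)
  }
})

test_that("coin-flip probabilities are symmetric, modal at n/2, and sum to 1", {
  for (n in c(10, 33, 64)) {
    k <- 0:n
    p <- coinflip_point_probability(k, n)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, rev(p), tolerance = 1e-14)          # k <-> n - k
    expect_equal(which.max(p) - 1, floor(n / 2))        # mode at the center
  }
  expect_error(coinflip_point_probability(5, 3), "k must")
})

test_that("rank permutation test reproduces the published disparity values", {
  t3 <- femoral_diver_records()
  pt <- permutation_rank_test(t3$cg, t3$status, n_perm = 4e4, seed = 31)
  # closed form for the top-rank depletion event at (59, 16, 16, 22) is
  # 0.001049; published Monte Carlo value 0.0011
  expect_equal(pt$p, 0.00105, tolerance = 0.5)
  expect_equal(unname(pt$observed), c(16, 22))
  expect_identical(pt$minority, "extant")

  # closed-form check of the permutation estimate
  closed <- exp(lchoose(59 - 21, 16) - lchoose(59, 16)) +
    6 * exp(lchoose(59 - 21, 15) - lchoose(59, 16))
  expect_equal(pt$p, closed, tolerance = 0.35)
})

test_that("rank permutation test is null-uniform and monotone-invariant", {
  set.seed(77)
  # under random labels the p-values are roughly uniform
  ps <- vapply(1:40, function(i) {
    v <- stats::runif(30)
    lab <- sample(rep(c("a", "b"), c(20, 10)))
    suppressWarnings(permutation_rank_test(v, lab, n_perm = 2000,
                                           statistic = "rank_sum")$p)
  }, 0)
  expect_gt(median(ps), 0.25)
  expect_lt(median(ps), 0.75)

  # monotone transform of values leaves the statistic untouched
  v <- stats::rlnorm(25)
  lab <- rep(c("a", "b"), c(17, 8))
  p1 <- suppressWarnings(permutation_rank_test(v, lab, n_perm = 3000, seed = 4)$p)
  p2 <- suppressWarnings(permutation_rank_test(log(v), lab, n_perm = 3000, seed = 4)$p)
  expect_identical(p1, p2)

  # perfectly depleted minority is at the resolution floor
  v2 <- c(stats::runif(18, 0.5, 1), stats::runif(5, 0, 0.4))
  lab2 <- rep(c("hi", "lo"), c(18, 5))
  p3 <- permutation_rank_test(v2, lab2, n_perm = 20000, seed = 9)$p
  expect_lt(p3, 0.005)
  expect_error(permutation_rank_test(v2, rep("hi", 23)), "two levels")
})

test_that("BCa reduces to the percentile method for symmetric samples", {
  set.seed(13)
  x <- rnorm(400)
  boots <- vapply(1:4000, function(b) mean(sample(x, replace = TRUE)), 0)
  ci <- bca_interval(boots, mean, x)
  # endpoints within 0.5 percentile points of the raw percentile interval
  expect_lt(abs(mean(boots <= ci$lo) - 0.025), 0.005)
  expect_lt(abs(mean(boots <= ci$hi) - 0.975), 0.005)
  expect_lt(abs(ci$bias_correction), 0.1)
  expect_lt(abs(ci$acceleration), 0.05)

  # all-equal replicates collapse to a flagged degenerate interval
  d <- suppressWarnings(bca_interval(rep(3, 200), mean, rep(3, 10)))
  expect_true(d$degenerate)
  expect_equal(d$lo, 3); expect_equal(d$hi, 3)
})

test_that("bootstrap runs are deterministic and sized exactly", {
  ds <- toy_dataset(n1 = 8, n2 = 8, seed = 55)
  part <- partition_classes(ds, "F0D0_vs_F0D2")
  ens <- random_tree_ensemble(star_tree(part$taxon_id), n = 3, seed = 2)
  b1 <- bootstrap_pfda(part, ens, n_trials = 15, lambda = 0.05, seed = 42,
                       compute_intervals = FALSE)
  b2 <- bootstrap_pfda(part, ens, n_trials = 15, lambda = 0.05, seed = 42,
                       compute_intervals = FALSE)
  expect_identical(b1$metrics, b2$metrics)          # bitwise reproducible
  expect_equal(nrow(b1$metrics), 15 * 3)            # trials x trees, exact
})

test_that("separated classes give a degenerate bootstrap accuracy of 1", {
  set.seed(3)
  # d/sigma = 5: essentially disjoint classes
  pts <- sim_two_class(10, sigma = 0.34, d = 1.7, seed = 3)
  ds <- tibble::tibble(
    taxon_id = sprintf("p%02d", 1:20),
    md_mm = 10^pts$x, cg = stats::plogis(pts$y),
    fly_code = "0", dive_code = rep(c("0", "2"), each = 10),
    status = "unknown", role = "train")
  part <- partition_classes(ds, "F0D0_vs_F0D2")
  bs <- bootstrap_pfda(part, star_tree(part$taxon_id), n_trials = 60,
                       lambda = 0, seed = 8)
  acc <- bs$intervals[bs$intervals$metric == "accuracy", ]
  expect_equal(acc$median, 1)
  expect_equal(acc$lo, 1)
  expect_equal(acc$hi, 1)
})

test_that("bootstrap interval width shrinks as the dataset grows", {
  widths <- vapply(c(30, 60, 120), function(n) {
    pts <- sim_two_class(n, sigma = 1.414, d = 1.7, seed = 100 + n)
    ds <- tibble::tibble(
      taxon_id = sprintf("q%03d", seq_len(2 * n)),
      md_mm = 10^pts$x, cg = stats::plogis(pts$y),
      fly_code = "0", dive_code = rep(c("0", "2"), each = n),
      status = "unknown", role = "train")
    part <- partition_classes(ds, "F0D0_vs_F0D2")
    bs <- bootstrap_pfda(part, star_tree(part$taxon_id), n_trials = 120,
                         lambda = 0, seed = n, compute_intervals = FALSE)
    diff(stats::quantile(bs$metrics$accuracy, c(0.025, 0.975), names = FALSE))
  }, 0)
  expect_true(all(diff(widths) < 0))
})
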