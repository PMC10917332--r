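test_that("relative range matches its published anchors", {
  # manatee rib series: published min/max/mean
  expect_equal(relative_range(c(0.8389, 0.9962), center = 0.9109), 17.3,
               tolerance = 5e-3)
  # threshold-sensitivity triple
  expect_equal(relative_range(c(0.888, 0.849, 0.804)), 9.9, tolerance = 5e-3)
  expect_equal(relative_range(c(0.5, 0.5, 0.5)), 0)
  # scale invariance
  v <- c(0.4, 0.7, 0.55)
  expect_equal(relative_range(v), relative_range(100 * v), tolerance = 1e-12)
  expect_error(relative_range(0.5), "at least 2")
})

test_that("the variation table reproduces its published medians", {
  entries <- cg_variation_entries()
  expect_equal(nrow(entries), 19)
  # recomputed per-entry ranges match the published column to print precision
  rr <- vapply(entries$cg, relative_range, 0)
  expect_true(all(abs(rr - entries$published_range) < 0.7))
  expect_equal(median_relative_range(entries), 18.6, tolerance = 5e-3)
  # trivial cases
  one <- entries[3, ]
  expect_equal(median_relative_range(one), relative_range(one$cg[[1]]))
  two <- tibble::tibble(cg = list(NULL, NULL), published_range = c(10, 20))
  expect_equal(median_relative_range(two), 15)
})

test_that("class summaries compute between-class relative range", {
  ds <- toy_dataset(seed = 5)
  part <- partition_classes(ds, "F0D0_vs_F0D2")
  s <- class_cg_summary(part)
  m1 <- mean(part$cg[part$class == 1]); m2 <- mean(part$cg[part$class == 2])
  expect_equal(unname(s$class_means["class1"]), m1)
  expect_equal(s$between_class_range, (m2 - m1) / mean(c(m1, m2)) * 100)
  # identical classes have zero between-class range
  same <- part
  same$cg <- 0.7
  expect_equal(class_cg_summary(same)$between_class_range, 0)
})

test_that("allometric regression matches the published nothosaur fit", {
  t3 <- femoral_diver_records()
  noth <- t3[grepl("^Nothosaurus", t3$taxon_id), ]
  fit <- ols_allometry(noth)
  expect_equal(fit$n, 6)
  expect_equal(fit$r2, 0.96, tolerance = 0.01)            # published 0.96
  expect_equal(fit$x_intercept, 103, tolerance = 0.01)    # published 103 mm
  expect_lt(fit$slope, 0)                                 # inverse correlation

  # noiseless line: exact recovery, and closed-form agreement
  md <- c(10, 20, 30, 40, 50)
  exact <- ols_allometry(tibble::tibble(md_mm = md, cg = 1 - 0.01 * md))
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  expect_equal(exact$x_intercept, 100, tolerance = 1e-9)
  sxy <- sum((md - mean(md)) * (1 - 0.01 * md - mean(1 - 0.01 * md)))
  sxx <- sum((md - mean(md))^2)
  expect_equal(exact$slope, sxy / sxx, tolerance = 1e-12)
  expect_error(ols_allometry(tibble::tibble(md_mm = c(5, 5, 5),
                                            cg = c(0.1, 0.2, 0.3))),
               "constant diameter")
})

test_that("the variant grid reproduces all 24 published rows", {
  v <- make_spinosaurid_variants()
  expect_equal(nrow(v), 24)
  expect_equal(sum(v$dataset == "femur"), 18)
  expect_equal(sum(v$dataset == "rib"), 6)
  # deterministic
  expect_identical(v, make_spinosaurid_variants())

  grab <- function(id, ds) v[v$variant_id == id & v$dataset == ds, ]
  # allometric diameter scaling: 81.52 * (1/0.72)^1.5 = 133.434
  expect_equal(grab("Spinosaurus 5", "femur")$md_mm, 133.434, tolerance = 1e-5)
  expect_equal(grab("Spinosaurus 5", "femur")$cg, 0.968)
  expect_equal(grab("Spinosaurus 2", "rib")$md_mm, 57.45, tolerance = 1e-4)
  # compactness scaling by 0.9
  expect_equal(grab("Baryonyx 1", "rib")$cg, 0.8289, tolerance = 1e-12)
  expect_equal(grab("Spinosaurus 1", "rib")$cg, 0.838, tolerance = 1e-12)
  # published bases carried through unchanged (variant 0 rows)
  base <- spinosaurid_test_points()
  for (i in seq_len(nrow(base))) {
    row <- grab(paste(base$taxon[i], 0), base$dataset[i])
    expect_equal(row$md_mm, base$md_mm[i])
    expect_equal(row$cg, base$cg[i])
  }
  # replacement-valued rows as printed
  expect_equal(grab("Suchomimus 1", "femur")$cg, 0.628)
  expect_equal(grab("Suchomimus 2", "femur")$md_mm, 146.4)
  expect_equal(grab("Baryonyx 3", "femur")$cg, 0.767)
})

test_that("variant evaluation flags boundary points and supports clear ones", {
  ds <- toy_dataset(n1 = 10, n2 = 10, seed = 66)
  part <- partition_classes(ds, "F0D0_vs_F0D2")
  ens <- random_tree_ensemble(star_tree(c(part$taxon_id, "probe")),
                              n = 3, seed = 1)
  m2 <- c(10^mean(log10(part$md_mm[part$class == 2])),
          mean(part$cg[part$class == 2]))
  mid <- c(10^mean(log10(part$md_mm)),
           mean(tapply(part$cg, part$class, mean)))
  variants <- tibble::tibble(
    variant_id = c("at_centroid_2", "on_boundary"),
    md_mm = c(m2[1], mid[1]), cg = c(m2[2], mid[2]))
  ev <- evaluate_variants(variants, part, ens, test_tip = "probe",
                          n_trials = 40, lambda = 0.02, seed = 12)
  expect_equal(nrow(ev), 2)
  # clear separation: centroid probe strongly supported
  expect_gt(ev$median_p2[1], 0.95)
  # boundary probe hovers near one half and is never strongly supported
  expect_lt(abs(ev$median_p2[2] - 0.5), 0.2)
  expect_false(ev$strong_support[2])
})
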