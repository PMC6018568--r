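test_that("bootstrap index draws have the documented distributional behaviour", {
  set.seed(41)
  # without replacement at full size: a permutation of all indices
  idx <- draw_bootstrap_indices(360, 360, with_replacement = FALSE)
  expect_setequal(idx, 1:360)
  expect_error(draw_bootstrap_indices(10, 11, with_replacement = FALSE),
               "without replacement")

  # occupancy: expected distinct count for 30-of-360 with replacement
  distinct <- vapply(1:5000, function(i)
    length(unique(draw_bootstrap_indices(360, 30))), numeric(1))
  expected <- 360 * (1 - (359 / 360)^30)
  expect_lt(abs(mean(distinct) - expected), 0.2)
})

test_that("the resampling study is reproducible and seeded per record", {
  fx <- test_fixed_cohort()
  a <- run_resampling_study(fx$cohort, fx$lesion_load, sizes = c(30, 60),
                            B = 50, seed = 5L)
  b <- run_resampling_study(fx$cohort, fx$lesion_load, sizes = c(30, 60),
                            B = 50, seed = 5L)
  expect_identical(a, b)
  expect_error(run_resampling_study(fx$cohort, fx$lesion_load, B = 10),
               "seed")

  # one record reproduced in isolation from its stored sub-seed
  rec <- a[17, ]
  set.seed(rec$seed_used)
  idx <- draw_bootstrap_indices(nrow(fx$cohort), rec$size)
  pc <- partial_correlation(fx$cohort$score_repn[idx], fx$lesion_load[idx],
                            covariate_matrix(fx$cohort)[idx, ])
  expect_equal(pc$r2, rec$r2, tolerance = 1e-12)
  expect_equal(pc$p_two_sided, rec$p, tolerance = 1e-12)
})

test_that("the identity resample returns the pinned full-sample estimate", {
  fx <- test_fixed_cohort()
  rec <- run_resampling_study(fx$cohort, fx$lesion_load, sizes = 360,
                              B = 1, with_replacement = FALSE, seed = 6L)
  expect_equal(rec$r2, 0.11, tolerance = 1e-10)
  expect_equal(rec$sign, -1L)
})

test_that("significance summaries partition the records with coherent moments", {
  fx <- test_fixed_cohort()
  rec <- run_resampling_study(fx$cohort, fx$lesion_load, sizes = c(30, 90),
                              B = 400, seed = 8L)
  sm <- summarize_by_significance(rec, alphas = c(0.05, 0.001))
  for (size in c(30, 90)) for (alpha in c(0.05, 0.001)) {
    cell <- sm[sm$size == size & sm$alpha == alpha, ]
    expect_equal(sum(cell$count), 400L)
    full <- cell[!is.na(cell$mean_r2), ]
    expect_true(all(full$min_r2 <= full$median_r2 & full$median_r2 <= full$max_r2))
  }
  # significant strata never dip below the closed-form floor
  sig <- sm[sm$group == "significant" & sm$count > 0, ]
  for (i in seq_len(nrow(sig)))
    expect_gte(sig$min_r2[i], critical_r2(sig$size[i], 5, sig$alpha[i]))
  # an all-non-significant stratum shows count 0 and NA moments
  null_rec <- rec[rec$p > 0.9, ]
  sm0 <- summarize_by_significance(null_rec, alphas = 0.05)
  s0 <- sm0[sm0$group == "significant", ]
  expect_true(all(s0$count == 0L))
  expect_true(all(is.na(s0$mean_r2)))
})

test_that("credible-interval classification partitions each size", {
  fx <- test_fixed_cohort()
  rec <- run_resampling_study(fx$cohort, fx$lesion_load, sizes = c(30, 360),
                              B = 300, seed = 9L)
  ci <- credible_interval_r2(0.11, 360, 5)
  cls <- classify_against_interval(rec, ci)
  for (size in c(30, 360)) {
    cells <- cls[cls$size == size, ]
    expect_equal(sum(cells$above + cells$within + cells$below), 300L)
  }
  # a record inside the interval is "within" regardless of p
  inside <- rec[rec$r2 >= ci$lower_r2 & rec$r2 <= ci$upper_r2, ]
  if (nrow(inside) > 0) {
    one <- inside[1, , drop = FALSE]
    class(one) <- "data.frame"
    c1 <- classify_against_interval(one, ci)
    expect_equal(sum(c1$within), 1L)
    expect_equal(sum(c1$above) + sum(c1$below), 0L)
  }
})

test_that("decile selection is nearest-rank with index tie-breaking", {
  # B = 11 distinct values: the eleven sorted records themselves
  rec <- data.frame(size = 30, replicate = 1:11,
                    r2 = c(0.5, 0.1, 0.3, 0.2, 0.05, 0.25, 0.15, 0.4, 0.35,
                           0.45, 0.0),
                    p = runif(11), sign = -1L)
  dec <- select_decile_resamples(rec)
  expect_equal(nrow(dec), 11L)
  expect_equal(dec$r2, sort(rec$r2))
  expect_true(all(diff(dec$r2) >= 0))

  # ties broken by lowest replicate index
  rec2 <- data.frame(size = 30, replicate = 1:12,
                     r2 = c(rep(0.2, 6), rep(0.8, 6)),
                     p = rep(0.5, 12), sign = -1L)
  dec2 <- select_decile_resamples(rec2)
  expect_equal(dec2$replicate[dec2$percentile == 0], 1L)
  expect_equal(dec2$replicate[dec2$percentile == 100], 12L)
  expect_error(select_decile_resamples(rec2[1:5, ]), "at least 11")
})

test_that("the median-decile R2 is stable across sizes while its p falls", {
  fx <- test_fixed_cohort()
  rec <- run_resampling_study(fx$cohort, fx$lesion_load,
                              sizes = c(30, 90, 360), B = 1000, seed = 10L)
  dec <- select_decile_resamples(rec)
  med <- dec[dec$percentile == 50, ]
  expect_lt(max(abs(med$r2 - 0.11)), 0.03)
  expect_true(all(diff(med$p[order(med$size)]) < 0))
})

test_that("rank-deficient resamples abort with a diagnostic", {
  fx <- test_fixed_cohort()
  bad <- fx$cohort
  bad$score_wpn <- bad$score_sema   # collinear covariates in every draw
  expect_error(run_resampling_study(bad, fx$lesion_load, sizes = 30, B = 10,
                                    seed = 11L),
               "rank deficiency")
})

test_that("ROI power summaries behave at the extremes and are order-invariant", {
  cfg <- calibrate_generator(generator_config(seed = 63L, n_patients = 120L,
                                              grid_shape = c(12, 12, 12),
                                              voxel_size_mm = 8))
  ch <- generate_cohort(cfg)
  load <- fix_sample_partial_r2(ch$cohort, ch$lesion_load, 0.3)
  vols <- generate_lesion_volumes(cfg, ch$cohort, load)
  X <- build_design_matrix(ch$cohort)
  roi_idx <- lesionboot:::roi_linear_indices(cfg$true_roi, cfg$grid_shape)
  roi <- list(voxels = roi_idx, grid = cfg$grid_shape)

  set.seed(64)
  idx <- sample(120, 90, replace = TRUE)
  pct <- roi_power_summary(vols$fuzzy, X, roi, idx, alpha_corrected = 0.05 / 500)
  expect_gte(pct, 0)
  expect_lte(pct, 100)

  roi_shuffled <- list(voxels = sample(roi_idx), grid = cfg$grid_shape)
  expect_equal(roi_power_summary(vols$fuzzy, X, roi_shuffled, idx,
                                 alpha_corrected = 0.05 / 500), pct)

  # null abnormality: observed per-voxel effects are tiny, power insufficient
  null_fz <- volume_set(matrix(rep(runif(120), each = length(roi_idx)) +
                                 matrix(runif(length(roi_idx) * 120, 0, 1e-4),
                                        length(roi_idx)),
                               length(roi_idx), 120),
                        c(length(roi_idx), 1, 1), 8,
                        ch$cohort$patient_id, "fuzzy")
  roi_null <- list(voxels = seq_along(roi_idx), grid = c(length(roi_idx), 1, 1))
  pct0 <- roi_power_summary(null_fz, X, roi_null, idx, alpha_corrected = 0.05 / 500)
  expect_equal(pct0, 0)
  expect_error(roi_power_summary(vols$fuzzy, X, list(voxels = integer(0)),
                                 idx, 0.05), "empty ROI")
})

test_that("with- and without-replacement studies agree for sizes below n", {
  fx <- test_fixed_cohort()
  sizes <- c(30, 90, 180)
  rw <- run_resampling_study(fx$cohort, fx$lesion_load, sizes = sizes,
                             B = 2000, seed = 12L)
  ro <- run_resampling_study(fx$cohort, fx$lesion_load, sizes = sizes,
                             B = 2000, with_replacement = FALSE, seed = 13L)
  for (s in sizes) {
    pw <- mean(rw$p[rw$size == s] < 0.05)
    po <- mean(ro$p[ro$size == s] < 0.05)
    expect_lt(abs(pw - po), 0.03)
  }
})

test_that("proportion significant increases with sample size", {
  fx <- test_fixed_cohort()
  rec <- run_resampling_study(fx$cohort, fx$lesion_load, B = 1500, seed = 14L)
  prop <- vapply(sort(unique(rec$size)), function(s)
    mean(rec$p[rec$size == s] < 0.05), numeric(1))
  expect_true(all(diff(prop) >= 0))
  expect_gte(sum(diff(prop) > 0), 3)
})

test_that("mean effect size across all records stays near the pinned value", {
  fx <- test_fixed_cohort()
  rec <- run_resampling_study(fx$cohort, fx$lesion_load, B = 1500, seed = 15L)
  for (s in c(90, 120, 180, 360))
    expect_lt(abs(mean(rec$r2[rec$size == s]) - 0.11), 0.02)
  m30 <- mean(rec$r2[rec$size == 30])
  expect_gt(m30, 0.11 - 0.01)
  expect_lt(m30, 0.11 + 0.04)
})
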