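test_that("configuration validates its invariants", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, target_partial_r2 = 1), "target_partial_r2")
  bad <- default_covariate_corr()
  bad[1, 2] <- 0.99
  expect_error(generator_config(seed = 1, covariate_corr = bad), "symmetric")
  bad <- matrix(0.999, 5, 5); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.999
  expect_error(calibrate_generator(generator_config(seed = 1, covariate_corr = bad)),
               "positive semi-definite")
  expect_error(generator_config(seed = 1, lesion_size_range = c(0.5, 100)), "1.5")
})

test_that("calibration reaches the target population partial R2 at large n", {
  # target 0.11 from the full-sample estimate; 0 and 0.5 as null and strong anchors
  targets <- c(0, 0.11, 0.5)
  for (tg in targets) {
    cfg <- calibrate_generator(
      generator_config(seed = 42L, n_patients = 100000L, target_partial_r2 = tg))
    if (tg == 0) expect_identical(cfg$calibration$effect_coef, 0)
    ch <- generate_cohort(cfg)
    pc <- partial_correlation(ch$cohort$score_repn, ch$lesion_load,
                              covariate_matrix(ch$cohort))
    if (tg == 0) {
      expect_lt(pc$r2, 50 / 100000)  # k/n-scale noise
    } else {
      expect_lt(abs(pc$r2 - tg), 0.005)
    }
  }
})

test_that("generated cohorts have T-score moments near 50/10 and valid sizes", {
  cfg <- test_calibrated_config()
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$cohort), 360L)
  for (col in c("score_repn", "score_wpn", "score_sema", "score_recm", "score_awp")) {
    expect_gt(mean(ch$cohort[[col]]), 48.5)
    expect_lt(mean(ch$cohort[[col]]), 51.5)
    expect_gt(sd(ch$cohort[[col]]), 9)
    expect_lt(sd(ch$cohort[[col]]), 11)
  }
  expect_true(all(ch$cohort$lesion_size_cm3 >= 1.5))
  expect_true(all(ch$cohort$lesion_size_cm3 <= 386.2))
  expect_true(all(ch$lesion_load >= 0 & ch$lesion_load <= 1))
  expect_false(anyNA(ch$cohort))
})

test_that("an empty cohort is returned without error at n = 0", {
  cfg <- calibrate_generator(generator_config(seed = 5L, n_patients = 0L))
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$cohort), 0L)
  expect_length(ch$lesion_load, 0L)
})

test_that("identical seed and config give bit-identical cohorts", {
  cfg <- test_calibrated_config()
  a <- generate_cohort(cfg, seed = 123L)
  b <- generate_cohort(cfg, seed = 123L)
  expect_identical(a, b)
  expect_error(generate_cohort(cfg, seed = NULL), "seed")
})

test_that("score clipping changes the SD by less than 2% under defaults", {
  cfg <- calibrate_generator(generator_config(seed = 9L, n_patients = 50000L,
                                              score_clip = c(-1e6, 1e6)))
  raw <- generate_cohort(cfg, seed = 11L)
  cfg2 <- calibrate_generator(generator_config(seed = 9L, n_patients = 50000L))
  clipped <- generate_cohort(cfg2, seed = 11L)
  for (col in c("score_repn", "score_wpn")) {
    expect_lt(abs(sd(raw$cohort[[col]]) - sd(clipped$cohort[[col]])) /
                sd(raw$cohort[[col]]), 0.02)
  }
})

test_that("mean in-sample partial R2 over repeated cohorts recovers the target", {
  # parameter recovery at the study's n for a spread of targets
  for (tg in c(0, 0.05, 0.11, 0.30)) {
    cfg <- calibrate_generator(generator_config(seed = 31L, target_partial_r2 = tg))
    r2s <- vapply(1:200, function(i) {
      ch <- generate_cohort(cfg, seed = derive_seed(31L, 1000L + i))
      partial_correlation(ch$cohort$score_repn, ch$lesion_load,
                          covariate_matrix(ch$cohort))$r2
    }, numeric(1))
    # small-sample bias of R2 is ~ (1 - rho2) * k_eff / n; allow 3 SE around
    # target + bias with bias bounded by 7/360
    bias_bound <- 7 / 360
    se <- sd(r2s) / sqrt(length(r2s))
    expect_lt(mean(r2s), tg + bias_bound + 3 * se)
    expect_gt(mean(r2s), tg - 3 * se)
  }
})

test_that("fix_sample_partial_r2 pins the in-sample R2 exactly", {
  fx <- test_fixed_cohort()
  pc <- partial_correlation(fx$cohort$score_repn, fx$lesion_load,
                            covariate_matrix(fx$cohort))
  expect_lt(abs(pc$r2 - 0.11), 1e-10)
  expect_equal(sign(pc$r_partial), -1)
  expect_true(all(fx$lesion_load >= 0 & fx$lesion_load <= 1))
})

test_that("fix_sample_partial_r2 is a fixed point at the sample's own R2", {
  cfg <- test_calibrated_config()
  ch <- generate_cohort(cfg, seed = 88L)
  pc0 <- partial_correlation(ch$cohort$score_repn, ch$lesion_load,
                             covariate_matrix(ch$cohort))
  adj <- fix_sample_partial_r2(ch$cohort, ch$lesion_load, pc0$r2)
  expect_lt(max(abs(adj - ch$lesion_load)), 1e-10)
})

test_that("fix_sample_partial_r2 at zero makes the load orthogonal to the target", {
  cfg <- test_calibrated_config()
  ch <- generate_cohort(cfg, seed = 89L)
  adj <- fix_sample_partial_r2(ch$cohort, ch$lesion_load, 0)
  orc <- oracle_partial(ch$cohort$score_repn, adj, covariate_matrix(ch$cohort))
  expect_lt(abs(orc$r), 1e-8)
  expect_gt(orc$p, 0.999)
})

test_that("lesion volumes reproduce load, size and overlap guarantees", {
  # default 4 mm grid (voxelisation on coarser grids breaks the size check)
  cfg <- calibrate_generator(generator_config(seed = 13L, n_patients = 120L))
  ch <- generate_cohort(cfg)
  vols <- generate_lesion_volumes(cfg, ch$cohort, ch$lesion_load)
  expect_s3_class(vols$fuzzy, "volume_set")
  expect_true(all(vols$fuzzy$data >= 0 & vols$fuzzy$data <= 1))
  expect_true(all(vols$binary$data %in% c(0, 1)))
  expect_identical(vols$binary$data, matrix(as.numeric(vols$fuzzy$data >= 0.3),
                                            nrow(vols$fuzzy$data)))

  roi_idx <- lesionboot:::roi_linear_indices(cfg$true_roi, cfg$grid_shape)
  roi_mean <- colMeans(vols$fuzzy$data[roi_idx, ])
  expect_lt(max(abs(roi_mean - ch$lesion_load)), 0.01)

  voxvol <- cfg$voxel_size_mm^3 / 1000
  est_size <- colSums(vols$binary$data) * voxvol
  pos <- ch$lesion_load > 0
  rel_err <- abs(est_size[pos] - ch$cohort$lesion_size_cm3[pos]) /
    ch$cohort$lesion_size_cm3[pos]
  expect_lt(max(rel_err), 0.10)

  overlap <- rowSums(vols$binary$data[roi_idx, ])
  expect_gte(min(overlap), 5)
})

test_that("zero latent load yields an all-zero volume and bad ROIs error", {
  cfg <- calibrate_generator(generator_config(seed = 14L, n_patients = 3L,
                                              grid_shape = c(10, 10, 10),
                                              voxel_size_mm = 4))
  ch <- generate_cohort(cfg)
  vols <- generate_lesion_volumes(cfg, ch$cohort, rep(0, 3))
  expect_true(all(vols$fuzzy$data == 0))
  expect_true(all(vols$binary$data == 0))
  bad <- cfg
  bad$true_roi <- matrix(c(11, 1, 1), 1)
  expect_error(generate_lesion_volumes(bad, ch$cohort, ch$lesion_load),
               "outside the grid")
})

test_that("volume synthesis is reproducible under a fixed seed", {
  cfg <- calibrate_generator(generator_config(seed = 15L, n_patients = 8L,
                                              grid_shape = c(12, 12, 12),
                                              voxel_size_mm = 4))
  ch <- generate_cohort(cfg)
  a <- generate_lesion_volumes(cfg, ch$cohort, ch$lesion_load, seed = 5L)
  b <- generate_lesion_volumes(cfg, ch$cohort, ch$lesion_load, seed = 5L)
  expect_identical(a$fuzzy$data, b$fuzzy$data)
})
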