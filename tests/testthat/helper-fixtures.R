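# Shared fixtures, built in code and cached across test files.

# calibrated default-condition generator (n = 360, target partial R2 0.11)
test_calibrated_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_generator(generator_config(seed = 7L))
    cache
  }
})

# the fixed study cohort: 360 patients, in-sample partial R2 pinned to 0.11
test_fixed_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- test_calibrated_config()
      ch <- generate_cohort(cfg)
      load <- fix_sample_partial_r2(ch$cohort, ch$lesion_load, 0.11)
      cache <<- list(cohort = ch$cohort, lesion_load = load, config = cfg)
    }
    cache
  }
})

covariate_matrix <- function(cohort, target = "score_repn") {
  cols <- c(setdiff(c("score_repn", "score_wpn", "score_sema",
                      "score_recm", "score_awp"), target), "lesion_size_cm3")
  as.matrix(cohort[, cols])
}

# independent two-stage residual-regression oracle for the partial correlation
oracle_partial <- function(y, x, C) {
  ry <- stats::resid(stats::lm(y ~ C))
  rx <- stats::resid(stats::lm(x ~ C))
  r <- stats::cor(ry, rx)
  n <- length(y)
  k <- ncol(C)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, r2 = r^2, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# random cohort table with independent columns (null structure)
random_null_cohort <- function(n) {
  data.frame(patient_id = sprintf("P%04d", seq_len(n)),
             score_repn = stats::rnorm(n, 50, 10),
             score_wpn = stats::rnorm(n, 50, 10),
             score_sema = stats::rnorm(n, 50, 10),
             score_recm = stats::rnorm(n, 50, 10),
             score_awp = stats::rnorm(n, 50, 10),
             lesion_size_cm3 = stats::rlnorm(n, 4, 0.8),
             stringsAsFactors = FALSE)
}

full_mask <- function(grid_shape) {
  structure(list(in_mask = array(TRUE, grid_shape),
                 n_voxels = prod(grid_shape), min_patients = 1),
            class = "analysis_mask")
}
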