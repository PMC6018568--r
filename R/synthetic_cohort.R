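# Synthetic cohort generator: behavioural T-scores, lesion sizes and latent
# region-of-interest lesion load with a calibrated population partial R2
# between lesion load and the target score given the five covariates
# (four nuisance scores + lesion size).
#
# Joint model: a 6-dimensional Gaussian copula drives (latent load, four
# nuisance z-scores, lesion-size z). Lesion load is the probability
# transform of its latent (Uniform[0,1] marginally), nuisance scores are
# 50 + 10 z clipped to score_clip, lesion size is a moment-matched
# lognormal clipped to lesion_size_range. The target score is then built as
#   Y = 50 + 10 * ( sqrt(w) G + s sqrt(rho2 (1-w)) U/sd(U)
#                   + sqrt((1-rho2)(1-w)) e )
# where G is a unit-variance combination of the standardized covariates, U
# is the population residual of lesion load on the covariates, s the effect
# sign and w the covariate share of variance. Residualizing Y on the
# covariates removes G exactly and leaves U and e, so the population
# squared partial correlation between load and Y given the covariates is
# rho2 by construction.

SCORE_COLS <- c("score_repn", "score_wpn", "score_sema", "score_recm", "score_awp")
NUISANCE_COLS <- SCORE_COLS[-1]
COVARIATE_COLS <- c(NUISANCE_COLS, "lesion_size_cm3")

#' Lognormal parameters matched to a mean and standard deviation
#' @param mean,sd target moments on the natural scale (cm^3).
#' @return list with \code{mu} and \code{sigma} on the log scale.
#' @keywords internal
lnorm_params_from_moments <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Configuration for the synthetic cohort generator
#'
#' Builds a generator configuration with defaults emulating the study
#' conditions: T-scores with mean 50 and SD 10 clipped to [10, 90], lesion
#' sizes from a lognormal moment-matched to mean 85.7 / SD 87.6 cm^3 and
#' clipped to [1.5, 386.2] cm^3, a designated cubic true region of interest
#' at the grid centre, and a target population partial R2 of 0.11 for the
#' lesion-load effect on the target score (negative direction: more damage,
#' lower score).
#'
#' @param n_patients cohort size (default 360).
#' @param target_partial_r2 population squared partial correlation between
#'   true-ROI lesion load and the target score given the 5 covariates.
#' @param effect_sign -1 (default) or +1.
#' @param covariate_corr 5x5 correlation matrix of (4 nuisance scores,
#'   lesion size) on the latent Gaussian scale; must be PSD with unit
#'   diagonal.
#' @param load_covariate_corr length-5 vector of latent correlations of
#'   lesion load with the 5 covariates.
#' @param covariate_share fraction of target-score variance carried by the
#'   covariates (default 0.3).
#' @param score_mean,score_sd T-score location and scale.
#' @param score_clip length-2 clipping bounds for all scores.
#' @param lesion_size_mean,lesion_size_sd moments of the lesion-size
#'   distribution in cm^3, converted internally to lognormal parameters.
#' @param lesion_size_range clipping range in cm^3 (minimum >= 1.5 mirrors
#'   the inclusion rule of lesions greater than 1 cm^3 after excluding the
#'   smallest ones).
#' @param grid_shape voxel counts per axis for the lesion volumes.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param true_roi integer matrix of 1-based voxel indices (columns i, j,
#'   k); default a 3x3x3 block at the grid centre.
#' @param binary_threshold fuzzy value at or above which a voxel counts as
#'   lesioned in the binary volume (default 0.3).
#' @param impairment_cutoffs per-task T-score impairment cut-offs, stored
#'   as metadata only and never used in inference.
#' @param calib_n Monte-Carlo sample size used by
#'   \code{\link{calibrate_generator}}.
#' @param seed integer master seed (mandatory).
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(n_patients = 360,
                             target_partial_r2 = 0.11,
                             effect_sign = -1,
                             covariate_corr = default_covariate_corr(),
                             load_covariate_corr = c(-0.2, -0.2, -0.2, -0.2, 0.5),
                             covariate_share = 0.3,
                             score_mean = 50, score_sd = 10,
                             score_clip = c(10, 90),
                             lesion_size_mean = 85.7, lesion_size_sd = 87.6,
                             lesion_size_range = c(1.5, 386.2),
                             grid_shape = c(40, 48, 40),
                             voxel_size_mm = 4,
                             true_roi = NULL,
                             binary_threshold = 0.3,
                             impairment_cutoffs = c(score_repn = 43.9, score_wpn = 51.4,
                                                    score_sema = 52.1, score_recm = 48.1,
                                                    score_awp = 51.7),
                             calib_n = 200000L,
                             seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory (reproducibility contract)")
  stopifnot_scalar_prob(target_partial_r2, "target_partial_r2", open_upper = TRUE)
  if (!effect_sign %in% c(-1, 1)) stop("'effect_sign' must be -1 or +1")
  if (!is_scalar_number(covariate_share) || covariate_share < 0 || covariate_share >= 1)
    stop("'covariate_share' must be in [0, 1)")
  covariate_corr <- as.matrix(covariate_corr)
  check_correlation_matrix(covariate_corr, 5L)
  if (length(load_covariate_corr) != 5L) stop("'load_covariate_corr' must have length 5")
  if (lesion_size_range[1] < 1.5)
    stop("lesion_size_range minimum must be >= 1.5 cm^3 (inclusion rule)")
  if (is.null(true_roi)) true_roi <- default_true_roi(grid_shape)
  true_roi <- as.matrix(true_roi)
  if (ncol(true_roi) != 3L) stop("'true_roi' must be an n x 3 matrix of voxel indices")
  if (!is_scalar_number(binary_threshold) || binary_threshold <= 0 || binary_threshold >= 1)
    stop("'binary_threshold' must be in (0, 1)")
  lp <- lnorm_params_from_moments(lesion_size_mean, lesion_size_sd)
  cfg <- list(
    n_patients = as.integer(n_patients),
    target_partial_r2 = target_partial_r2,
    effect_sign = effect_sign,
    covariate_corr = covariate_corr,
    load_covariate_corr = load_covariate_corr,
    covariate_share = covariate_share,
    score_mean = score_mean, score_sd = score_sd,
    score_clip = score_clip,
    lesion_size_lognormal_params = lp,
    lesion_size_range = lesion_size_range,
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    true_roi = true_roi,
    binary_threshold = binary_threshold,
    impairment_cutoffs = impairment_cutoffs,
    calib_n = as.integer(calib_n),
    seed = as.integer(seed),
    calibration = NULL
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Default latent correlation matrix for (4 nuisance scores, lesion size)
#' @return a 5x5 correlation matrix: 0.4 among scores, -0.3 score vs size.
#' @export
default_covariate_corr <- function() {
  R <- matrix(0.4, 5, 5)
  R[5, 1:4] <- R[1:4, 5] <- -0.3
  diag(R) <- 1
  dimnames(R) <- list(COVARIATE_COLS, COVARIATE_COLS)
  R
}

default_true_roi <- function(grid_shape) {
  ctr <- ceiling(grid_shape / 2)
  g <- expand.grid(i = ctr[1] + (-1:1), j = ctr[2] + (-1:1), k = ctr[3] + (-1:1))
  as.matrix(g)
}

check_correlation_matrix <- function(R, p) {
  if (nrow(R) != p || ncol(R) != p) stop(sprintf("correlation matrix must be %dx%d", p, p))
  if (max(abs(R - t(R))) > 1e-10) stop("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop("correlation matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("correlation matrix is not positive semi-definite")
  invisible(R)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic lesion-cohort generator configuration\n")
  cat(sprintf("  n_patients: %d, target partial R2: %.3f (sign %+d)\n",
              x$n_patients, x$target_partial_r2, x$effect_sign))
  cat(sprintf("  grid: %s voxels at %.1f mm, true ROI: %d voxels\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm, nrow(x$true_roi)))
  cat(sprintf("  calibrated: %s\n", !is.null(x$calibration)))
  invisible(x)
}

# full 6x6 latent correlation (load first, then the 5 covariates)
joint_latent_corr <- function(config) {
  R <- matrix(0, 6, 6)
  R[2:6, 2:6] <- config$covariate_corr
  R[1, 2:6] <- R[2:6, 1] <- config$load_covariate_corr
  diag(R) <- 1
  R
}

# draw the latent 6-dim Gaussian and map to observed marginals
draw_latents <- function(config, n, chol_R) {
  Z <- matrix(stats::rnorm(n * 6), n, 6) %*% chol_R
  lp <- config$lesion_size_lognormal_params
  load <- stats::pnorm(Z[, 1])
  nuis <- config$score_mean + config$score_sd * Z[, 2:5]
  nuis <- pmin(pmax(nuis, config$score_clip[1]), config$score_clip[2])
  size <- stats::qlnorm(stats::pnorm(Z[, 6]), lp$mu, lp$sigma)
  size <- pmin(pmax(size, config$lesion_size_range[1]), config$lesion_size_range[2])
  list(load = load, nuisance = nuis, size = size)
}

#' Calibrate the generator's effect coefficients
#'
#' Fixes the coefficients of the target-score model so that, in the implied
#' infinite population, the squared partial correlation between true-ROI
#' lesion load and the target score given the 5 covariates equals
#' \code{target_partial_r2}. The population regression of lesion load on
#' the covariates (needed for the residual direction and its SD) has no
#' closed form after the marginal transforms, so it is estimated once from
#' a large Monte-Carlo sample (\code{calib_n} draws on a dedicated
#' sub-seed); everything downstream then uses the stored coefficients.
#'
#' @param config a \code{\link{generator_config}}.
#' @param target_partial_r2 optional override of the configured target.
#' @return the config with its \code{calibration} slot filled.
#' @export
calibrate_generator <- function(config, target_partial_r2 = config$target_partial_r2) {
  stopifnot(inherits(config, "generator_config"))
  stopifnot_scalar_prob(target_partial_r2, "target_partial_r2", open_upper = TRUE)
  R <- joint_latent_corr(config)
  check_correlation_matrix(R, 6L)
  chol_R <- chol(R)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 101L))
  lat <- draw_latents(config, config$calib_n, chol_R)

  C <- cbind(lat$nuisance, lat$size)
  X <- cbind(1, C)
  fit <- stats::lm.fit(X, lat$load)
  beta_load <- unname(fit$coefficients)
  sd_U <- stats::sd(fit$residuals)

  cov_mean <- colMeans(C)
  cov_sd <- apply(C, 2, stats::sd)
  wvec <- c(1, 1, 1, 1, -1)     # target score rises with other scores, falls with size
  Cstd <- sweep(sweep(C, 2, cov_mean), 2, cov_sd, "/")
  G0 <- drop(Cstd %*% wvec)
  scale_G <- stats::sd(G0)

  w <- config$covariate_share
  rho2 <- target_partial_r2
  config$target_partial_r2 <- rho2
  config$calibration <- list(
    chol_R = chol_R,
    beta_load = beta_load,
    sd_U = sd_U,
    cov_mean = cov_mean, cov_sd = cov_sd,
    wvec = wvec, scale_G = scale_G,
    covariate_share = w,
    effect_coef = config$effect_sign * sqrt(rho2 * (1 - w)),
    noise_sd = sqrt((1 - rho2) * (1 - w))
  )
  config
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cohort table with latent lesion load
#'
#' Draws \code{n_patients} rows: five behavioural T-scores (mean ~50, SD
#' ~10 before clipping), lesion size in cm^3 from the clipped lognormal,
#' and the latent per-patient true-ROI lesion load in [0,1] that the
#' calibrated effect model ties to the target score.
#'
#' @param config a calibrated \code{\link{generator_config}}.
#' @param seed integer seed for this draw (mandatory; defaults to a
#'   sub-seed of the config seed).
#' @return a list with \code{cohort} (data.frame with columns
#'   \code{patient_id}, the five score columns and \code{lesion_size_cm3})
#'   and \code{lesion_load} (numeric vector).
#' @export
generate_cohort <- function(config, seed = derive_seed(config$seed, 202L)) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$calibration))
    stop("config is not calibrated; call calibrate_generator() first")
  if (is.null(seed)) stop("'seed' is mandatory (reproducibility contract)")
  cal <- config$calibration
  n <- config$n_patients

  if (n == 0L) {
    empty <- data.frame(patient_id = character(0),
                        score_repn = numeric(0), score_wpn = numeric(0),
                        score_sema = numeric(0), score_recm = numeric(0),
                        score_awp = numeric(0), lesion_size_cm3 = numeric(0),
                        stringsAsFactors = FALSE)
    return(list(cohort = empty, lesion_load = numeric(0), seed = as.integer(seed)))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lat <- draw_latents(config, n, cal$chol_R)

  C <- cbind(lat$nuisance, lat$size)
  U <- lat$load - drop(cbind(1, C) %*% cal$beta_load)
  Cstd <- sweep(sweep(C, 2, cal$cov_mean), 2, cal$cov_sd, "/")
  G <- drop(Cstd %*% cal$wvec) / cal$scale_G
  y_std <- sqrt(cal$covariate_share) * G +
    cal$effect_coef * U / cal$sd_U +
    cal$noise_sd * stats::rnorm(n)
  y <- config$score_mean + config$score_sd * y_std
  y <- pmin(pmax(y, config$score_clip[1]), config$score_clip[2])

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    score_repn = y,
    score_wpn = lat$nuisance[, 1],
    score_sema = lat$nuisance[, 2],
    score_recm = lat$nuisance[, 3],
    score_awp = lat$nuisance[, 4],
    lesion_size_cm3 = lat$size,
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, lesion_load = lat$load, seed = as.integer(seed))
}

#' Adjust lesion load so the in-sample partial R2 is exact
#'
#' Rotates the lesion-load vector in the plane spanned by its
#' covariate-residualized component and the covariate-residualized target
#' score so that the in-sample squared partial correlation equals
#' \code{exact_r2} to machine precision, then (only if needed) affinely
#' re-maps the adjusted values into [0, 1] — an order-preserving map that
#' leaves the partial correlation untouched. Passing the sample's own
#' current R2 returns the input unchanged.
#'
#' @param cohort cohort data.frame (see \code{\link{generate_cohort}}).
#' @param lesion_load per-patient lesion-load fractions.
#' @param exact_r2 required in-sample squared partial correlation.
#' @param target name of the target score column (default
#'   \code{"score_repn"}).
#' @param effect_sign sign the adjusted partial correlation should carry;
#'   by default the sign of the unadjusted sample correlation (or -1 if
#'   that is zero).
#' @return the adjusted lesion-load vector.
#' @export
fix_sample_partial_r2 <- function(cohort, lesion_load, exact_r2,
                                  target = "score_repn", effect_sign = NULL) {
  stopifnot_scalar_prob(exact_r2, "exact_r2", open_upper = TRUE)
  y <- cohort[[target]]
  # the 5-covariate set: the 4 other scores + lesion size
  covs <- as.matrix(cohort[, c(setdiff(SCORE_COLS, target), "lesion_size_cm3")])
  n <- nrow(covs)
  k <- ncol(covs)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  X <- cbind(1, covs)
  res <- ls_residuals(X, cbind(y, lesion_load))
  ey <- res[, 1]
  ex <- res[, 2]
  x_hat <- lesion_load - ex
  ney <- sqrt(sum(ey^2))
  nex <- sqrt(sum(ex^2))
  if (ney < 1e-12 || nex < 1e-12) stop("degenerate sample: residual vector is constant")
  ey_u <- ey / ney
  proj <- sum(ex * ey_u)
  r0 <- proj / nex
  ex_perp <- ex - proj * ey_u
  nperp <- sqrt(sum(ex_perp^2))
  if (nperp < 1e-12 && exact_r2 < 1)
    stop("exact_r2 infeasible: lesion load is collinear with the residualized target")
  if (is.null(effect_sign)) effect_sign <- if (r0 != 0) sign(r0) else -1
  ex_new <- nex * (effect_sign * sqrt(exact_r2) * ey_u +
                     sqrt(1 - exact_r2) * ex_perp / nperp)
  adj <- x_hat + ex_new
  if (min(adj) < 0 || max(adj) > 1) {
    adj <- (adj - min(adj)) / (max(adj) - min(adj))
  }
  adj
}
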