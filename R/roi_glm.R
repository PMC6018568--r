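# Voxel-wise mass-univariate regression of fuzzy abnormality on the six
# regressors (five behavioural T-scores + lesion size), family-wise-error
# thresholding of the map for the regressor of interest, and lesion-load
# extraction from the resulting region of interest.

T_SENTINEL <- 1e6

#' Build the design matrix for the voxel-wise regression
#'
#' Columns, in order: intercept, the five behavioural scores (nonword
#' repetition first — the regressor of interest), and lesion size.
#'
#' @param cohort cohort data.frame.
#' @return numeric matrix n x 7 of full column rank, with column names.
#' @export
build_design_matrix <- function(cohort) {
  need <- c(SCORE_COLS, "lesion_size_cm3")
  if (!all(need %in% names(cohort)))
    stop("cohort is missing columns: ", paste(setdiff(need, names(cohort)), collapse = ", "))
  if (anyNA(cohort[, need])) stop("cohort contains missing values")
  X <- cbind(intercept = 1, as.matrix(cohort[, need]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

# t statistics for one design column across many response columns; shared
# hat matrix since the design is identical at every voxel
glm_t_stats <- function(X, Y, j, XtXinv = solve(crossprod(X))) {
  n <- nrow(X)
  p <- ncol(X)
  df <- n - p
  B <- XtXinv %*% crossprod(X, Y)
  rss <- colSums((Y - X %*% B)^2)
  sigma2 <- rss / df
  cjj <- XtXinv[j, j]
  coef_j <- B[j, ]
  se <- sqrt(sigma2 * cjj)
  t <- coef_j / se
  degen <- sigma2 < 1e-12 * max(1, mean(colMeans(Y^2)))
  if (any(degen)) {
    t[degen & abs(coef_j) > 1e-10] <-
      sign(coef_j[degen & abs(coef_j) > 1e-10]) * T_SENTINEL
    t[degen & abs(coef_j) <= 1e-10] <- 0
  }
  list(t = t, df = df, degenerate = degen)
}

#' Fit the voxel-wise general linear model
#'
#' Ordinary least squares of the fuzzy abnormality value on the seven
#' design columns at every in-mask voxel, returning the t statistic of the
#' regressor of interest. Voxels with (numerically) zero residual variance
#' get t = 0 when the coefficient is also zero, or a large-magnitude
#' sentinel when the fit is exact; both are flagged and excluded from any
#' downstream ROI.
#'
#' @param fuzzies fuzzy \code{\link{volume_set}}, patient order matching
#'   the design rows.
#' @param design matrix from \code{\link{build_design_matrix}}.
#' @param mask an \code{\link{analysis_mask}}.
#' @param regressor design column tested (default \code{"score_repn"}).
#' @return an object of class \code{voxel_stat_map}: list with \code{t}
#'   (per in-mask voxel), \code{df}, \code{voxel_index} (linear indices
#'   into the grid), \code{degenerate} flags, \code{contrast}.
#' @export
fit_voxelwise_glm <- function(fuzzies, design, mask, regressor = "score_repn") {
  stopifnot(inherits(fuzzies, "volume_set"), inherits(mask, "analysis_mask"))
  n <- ncol(fuzzies$data)
  if (nrow(design) != n) stop("design rows must match the number of volumes")
  if (n < 10) stop("need at least 10 patients for the voxel-wise fit")
  j <- match(regressor, colnames(design))
  if (is.na(j)) stop("regressor not found in design: ", regressor)
  vidx <- which(as.vector(mask$in_mask))
  if (length(vidx) == 0L) stop("empty analysis mask")
  Y <- t(fuzzies$data[vidx, , drop = FALSE])   # n x V
  st <- glm_t_stats(design, Y, j)
  if (any(st$degenerate))
    warning(sprintf("%d voxel(s) had zero residual variance; flagged", sum(st$degenerate)))
  structure(list(t = st$t, df = st$df, voxel_index = vidx,
                 degenerate = st$degenerate,
                 contrast = regressor, grid = fuzzies$dim),
            class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat(sprintf("<voxel_stat_map> %d voxels, df = %d, contrast = %s, t range [%.2f, %.2f]\n",
              length(x$t), x$df, x$contrast, min(x$t), max(x$t)))
  invisible(x)
}

#' Family-wise-error threshold and ROI extraction
#'
#' Thresholds the voxel t map controlling the family-wise error rate at
#' \code{alpha}, either by a Freedman-Lane max-statistic permutation null
#' (default) or by the deterministic Bonferroni bound. The ROI keeps only
#' voxels whose t statistic carries the hypothesised sign (negative by
#' default: more abnormality, lower score) and exceeds the threshold in
#' magnitude. The permutation scheme permutes the residuals of the reduced
#' model (all regressors except the one tested), so the null respects the
#' covariate structure.
#'
#' @param stats a \code{\link{fit_voxelwise_glm}} result.
#' @param design the design matrix used for the fit.
#' @param fuzzies the fuzzy \code{\link{volume_set}} used for the fit.
#' @param mask the \code{\link{analysis_mask}} used for the fit.
#' @param alpha family-wise error rate (default 0.05).
#' @param method "permutation_maxT" or "bonferroni".
#' @param n_perm number of permutations (>= 500).
#' @param seed RNG seed for the permutations (mandatory for the
#'   permutation method).
#' @param tails 1 (default, one-tailed in the hypothesised direction) or 2.
#' @param effect_sign hypothesised sign of the effect (-1 default).
#' @return an object of class \code{roi_mask}: list with \code{voxels}
#'   (linear grid indices), \code{n_voxels}, \code{threshold_used} (on
#'   \code{|t|}), \code{method}, \code{alpha}, \code{tails}.
#' @export
fwe_threshold <- function(stats, design, fuzzies, mask, alpha = 0.05,
                          method = c("permutation_maxT", "bonferroni"),
                          n_perm = 2000, seed = NULL, tails = 1,
                          effect_sign = -1) {
  method <- match.arg(method)
  stopifnot(inherits(stats, "voxel_stat_map"))
  stopifnot_scalar_prob(alpha, "alpha", open_upper = TRUE)
  if (alpha <= 0) stop("'alpha' must be in (0,1)")
  if (!tails %in% c(1, 2)) stop("'tails' must be 1 or 2")
  vidx <- stats$voxel_index
  nvox <- length(vidx)
  tobs <- stats$t

  if (method == "bonferroni") {
    thr <- stats::qt(1 - alpha / (tails * nvox), stats$df)
  } else {
    if (n_perm < 500) stop("need n_perm >= 500 for the permutation method")
    if ((n_perm + 1) * alpha < 1)
      stop("n_perm too small to resolve alpha = ", alpha)
    if (is.null(seed)) stop("'seed' is mandatory for the permutation method")
    j <- match(stats$contrast, colnames(design))
    X0 <- design[, -j, drop = FALSE]
    Y <- t(fuzzies$data[vidx, , drop = FALSE])
    qr0 <- qr(X0)
    fitted0 <- qr.fitted(qr0, Y)
    R0 <- Y - fitted0
    XtXinv <- solve(crossprod(design))
    n <- nrow(design)
    maxstat <- function(tv) {
      if (tails == 1) max(effect_sign * tv) else max(abs(tv))
    }
    obs_stat <- maxstat(tobs)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    null_max <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      Yp <- fitted0 + R0[perm, , drop = FALSE]
      tp <- glm_t_stats(design, Yp, j, XtXinv)$t
      null_max[b] <- maxstat(tp)
    }
    # observed statistic joins the null (exactness of the permutation test)
    null_all <- c(obs_stat, null_max)
    thr <- sort(null_all, decreasing = TRUE)[max(1L, floor(alpha * length(null_all)))]
  }

  keep <- sign(tobs) == effect_sign &
    (effect_sign * tobs) >= thr &
    abs(tobs) < T_SENTINEL & !stats$degenerate
  structure(list(voxels = vidx[keep], n_voxels = sum(keep),
                 threshold_used = thr, method = method, alpha = alpha,
                 tails = tails, effect_sign = effect_sign,
                 grid = stats$grid),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels (%s, alpha = %g, |t| threshold %.3f)\n",
              x$n_voxels, x$method, x$alpha, x$threshold_used))
  invisible(x)
}

#' Mean fuzzy abnormality over the ROI, per patient
#'
#' The lesion load: a single value per patient, the average fuzzy signal
#' across the ROI voxels.
#'
#' @param fuzzies fuzzy \code{\link{volume_set}}.
#' @param roi a \code{\link{fwe_threshold}} result (or any list with a
#'   \code{voxels} element of linear grid indices).
#' @return numeric vector of per-patient loads in [0, 1].
#' @export
extract_lesion_load <- function(fuzzies, roi) {
  stopifnot(inherits(fuzzies, "volume_set"))
  if (length(roi$voxels) == 0L) stop("empty ROI")
  colMeans(fuzzies$data[roi$voxels, , drop = FALSE])
}

#' Write a ROI mask as NIfTI with a JSON sidecar of settings
#' @param roi a \code{roi_mask}.
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   \code{.json}.
#' @param voxel_size_mm voxel size in mm.
#' @return invisibly, \code{path}.
#' @export
write_roi <- function(roi, path, voxel_size_mm) {
  arr <- array(0L, dim = roi$grid)
  arr[roi$voxels] <- 1L
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path, datatype = "uint8")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(n_voxels = roi$n_voxels, threshold_used = roi$threshold_used,
         method = roi$method, alpha = roi$alpha, tails = roi$tails,
         effect_sign = roi$effect_sign),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
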