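# The resampling study: thousands of bootstrap samples per sample size,
# each yielding the ROI-level partial correlation between lesion load and
# the target score given the five covariates; plus the summary tables
# (significance-split moments, credible-interval classification, decile
# selections) and the ROI power summary for selected resamples.

#' Draw bootstrap indices
#'
#' With replacement: i.i.d. uniform draws (the probability of being chosen
#' stays constant throughout). Without replacement: a uniform random
#' subset. Uses the current RNG state; seed the stream before calling for
#' reproducibility.
#'
#' @param n_total cohort size.
#' @param size resample size.
#' @param with_replacement logical (default TRUE).
#' @return integer vector of length \code{size}.
#' @export
draw_bootstrap_indices <- function(n_total, size, with_replacement = TRUE) {
  if (!with_replacement && size > n_total)
    stop("cannot draw more than n_total indices without replacement")
  sample.int(n_total, size, replace = with_replacement)
}

#' Run the bootstrap resampling study
#'
#' For each sample size, draws \code{B} bootstrap samples from the fixed
#' cohort and records the squared partial correlation, two-sided p value
#' and sign of the ROI lesion-load effect in each. Every record has its own
#' sub-seed (streamed from the master seed per size) so any single
#' replicate can be reproduced in isolation. Resamples whose design is rank
#' deficient are redrawn; if more than 1% of draws for a size need
#' redrawing the study aborts with a diagnostic.
#'
#' @param cohort the fixed cohort data.frame.
#' @param lesion_load per-patient ROI lesion load (typically fixed with
#'   \code{\link{fix_sample_partial_r2}}).
#' @param sizes resample sizes (default the study's six sizes).
#' @param B replicates per size (default 6000).
#' @param with_replacement logical (default TRUE).
#' @param seed master seed (mandatory).
#' @param target target score column.
#' @return data.frame of class \code{resample_records} with columns
#'   \code{size}, \code{replicate}, \code{r2}, \code{p}, \code{sign},
#'   \code{seed_used}; the redraw count is attached as attribute
#'   \code{n_redraws}.
#' @export
run_resampling_study <- function(cohort, lesion_load,
                                 sizes = c(30, 60, 90, 120, 180, 360),
                                 B = 6000, with_replacement = TRUE, seed,
                                 target = "score_repn") {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  if (B < 1) stop("'B' must be >= 1")
  n <- nrow(cohort)
  y <- cohort[[target]]
  covs <- as.matrix(cohort[, c(setdiff(SCORE_COLS, target), "lesion_size_cm3")])
  x <- lesion_load
  k <- ncol(covs)
  p_design <- k + 1L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  out <- vector("list", length(sizes))
  total_redraws <- 0L
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    df <- size - 2L - k
    if (df < 1) stop("resample size too small for the covariate set: ", size)
    set.seed(derive_seed(seed, 7000L + si))
    rec_seeds <- sample.int(2147483646L, B)
    r2 <- p <- numeric(B)
    sgn <- integer(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      set.seed(rec_seeds[b])
      repeat {
        idx <- draw_bootstrap_indices(n, size, with_replacement)
        Xb <- cbind(1, covs[idx, , drop = FALSE])
        fit <- stats::.lm.fit(Xb, cbind(y[idx], x[idx]))
        if (fit$rank == p_design) break
        redraws <- redraws + 1L
        if (redraws > 0.01 * B)
          stop(sprintf("persistent rank deficiency at size %d (%d redraws)", size, redraws))
      }
      ey <- fit$residuals[, 1]
      ex <- fit$residuals[, 2]
      den <- sqrt(sum(ey^2) * sum(ex^2))
      r <- if (den > 0) sum(ey * ex) / den else 0
      r <- max(-1, min(1, r))
      tt <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
      r2[b] <- r^2
      p[b] <- 2 * stats::pt(-abs(tt), df)
      sgn[b] <- if (r >= 0) 1L else -1L
    }
    total_redraws <- total_redraws + redraws
    out[[si]] <- data.frame(size = size, replicate = seq_len(B),
                            r2 = r2, p = p, sign = sgn,
                            seed_used = rec_seeds)
  }
  records <- do.call(rbind, out)
  attr(records, "n_redraws") <- total_redraws
  attr(records, "with_replacement") <- with_replacement
  class(records) <- c("resample_records", "data.frame")
  records
}

#' Summarise resample effect sizes split by significance
#'
#' For each sample size and alpha level, splits the records into
#' significant (p < alpha) and non-significant and reports the count and
#' the mean, median, minimum and maximum R2 of each stratum (NA moments
#' when a stratum is empty).
#'
#' @param records a \code{\link{run_resampling_study}} result.
#' @param alphas significance levels (default 0.05 and 0.001).
#' @return data.frame with columns \code{size}, \code{alpha},
#'   \code{group}, \code{count}, \code{mean_r2}, \code{median_r2},
#'   \code{min_r2}, \code{max_r2}.
#' @export
summarize_by_significance <- function(records, alphas = c(0.05, 0.001)) {
  if (nrow(records) == 0L) stop("no records")
  rows <- list()
  for (size in sort(unique(records$size))) {
    rs <- records[records$size == size, ]
    for (alpha in alphas) {
      sig <- rs$p < alpha
      for (grp in c("significant", "not_significant")) {
        sel <- if (grp == "significant") rs$r2[sig] else rs$r2[!sig]
        rows[[length(rows) + 1L]] <- data.frame(
          size = size, alpha = alpha, group = grp, count = length(sel),
          mean_r2 = if (length(sel)) mean(sel) else NA_real_,
          median_r2 = if (length(sel)) stats::median(sel) else NA_real_,
          min_r2 = if (length(sel)) min(sel) else NA_real_,
          max_r2 = if (length(sel)) max(sel) else NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Classify resample effect sizes against a credible interval
#'
#' Cross-tabulates each record by statistical significance (p < alpha) and
#' by the position of its R2 relative to the full-cohort credible interval
#' (above the upper bound / within / below the lower bound). The six cells
#' per size partition the B records.
#'
#' @param records a \code{\link{run_resampling_study}} result.
#' @param interval a \code{\link{credible_interval_r2}} result.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns \code{size}, \code{significant},
#'   \code{above}, \code{within}, \code{below}.
#' @export
classify_against_interval <- function(records, interval, alpha = 0.05) {
  stopifnot(inherits(interval, "credible_interval"))
  rows <- list()
  for (size in sort(unique(records$size))) {
    rs <- records[records$size == size, ]
    pos <- ifelse(rs$r2 > interval$upper_r2, "above",
                  ifelse(rs$r2 < interval$lower_r2, "below", "within"))
    for (sig in c(TRUE, FALSE)) {
      sel <- pos[(rs$p < alpha) == sig]
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, significant = sig,
        above = sum(sel == "above"), within = sum(sel == "within"),
        below = sum(sel == "below"))
    }
  }
  do.call(rbind, rows)
}

#' Select the resamples sitting at each decile of the R2 distribution
#'
#' Nearest-rank (no interpolation) percentiles 0, 10, ..., 100 of the R2
#' distribution within each size; returns the actual record at each rank.
#' Ties in R2 are broken by the lowest replicate index.
#'
#' @param records a \code{\link{run_resampling_study}} result.
#' @return data.frame with columns \code{size}, \code{percentile},
#'   \code{replicate}, \code{r2}, \code{p}.
#' @export
select_decile_resamples <- function(records) {
  rows <- list()
  for (size in sort(unique(records$size))) {
    rs <- records[records$size == size, ]
    B <- nrow(rs)
    if (B < 11) stop("need at least 11 records per size")
    ord <- order(rs$r2, rs$replicate)
    for (q in seq(0, 100, 10)) {
      rank <- max(1L, as.integer(ceiling(q / 100 * B)))
      rec <- rs[ord[rank], ]
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, percentile = q, replicate = rec$replicate,
        r2 = rec$r2, p = rec$p)
    }
  }
  do.call(rbind, rows)
}

#' Percentage of ROI voxels with sufficient power in one resample
#'
#' For the patients of one selected resample, refits the voxel-wise model
#' at the ROI voxels, converts each voxel's t statistic into an observed
#' effect size (t^2 / (t^2 + df)), evaluates the analytic power of
#' detecting that effect at the corrected alpha with the resample's n, and
#' reports the percentage of ROI voxels whose power reaches the
#' sufficiency threshold.
#'
#' @param fuzzies fuzzy \code{\link{volume_set}} restricted to (or indexed
#'   by) the resample's patients: pass the full set plus \code{indices}.
#' @param design full-cohort design matrix.
#' @param roi a \code{roi_mask}.
#' @param indices patient indices of the resample.
#' @param alpha_corrected the multiple-comparison-corrected alpha (e.g.
#'   Bonferroni over the analysis mask).
#' @param power_threshold sufficiency cut-off (default 0.80).
#' @return the percentage (0-100) of ROI voxels with power at or above the
#'   threshold.
#' @export
roi_power_summary <- function(fuzzies, design, roi, indices, alpha_corrected,
                              power_threshold = 0.80) {
  stopifnot(inherits(fuzzies, "volume_set"))
  if (length(roi$voxels) == 0L) stop("empty ROI")
  stopifnot_scalar_prob(alpha_corrected, "alpha_corrected", open_upper = TRUE)
  Xs <- design[indices, , drop = FALSE]
  Ys <- t(fuzzies$data[roi$voxels, indices, drop = FALSE])
  j <- match("score_repn", colnames(design))
  st <- glm_t_stats(Xs, Ys, j)
  r2_vox <- st$t^2 / (st$t^2 + st$df)
  r2_vox[st$degenerate] <- 0
  r2_vox <- pmin(r2_vox, 1 - 1e-12)
  n_sub <- length(indices)
  k <- ncol(design) - 2L   # covariates beside intercept and tested regressor
  pw <- analytic_power(r2_vox, n_sub, k, alpha_corrected)
  100 * mean(pw >= power_threshold)
}
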