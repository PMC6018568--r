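# Partial-correlation effect sizes and the closed-form calculators built on
# the Fisher-z approximation. Conventions used throughout: with k covariates
# the partial correlation carries df = n - 2 - k, and the Fisher-z standard
# error of a partial correlation is 1/sqrt(n - k - 3).

#' Partial correlation between a score and lesion load given covariates
#'
#' Computes the partial correlation between \code{y} and \code{x} after
#' linearly removing \code{covariates} (plus an intercept) from both, the
#' associated t statistic on \code{n - 2 - k} degrees of freedom, and the
#' two-sided p value. The square of the partial correlation is the
#' proportion of variance in \code{y} explained uniquely by \code{x}.
#'
#' @param y numeric response vector (e.g. nonword repetition T-scores).
#' @param x numeric vector of the variable of interest (e.g. lesion load).
#' @param covariates numeric matrix (or data.frame) of nuisance variables,
#'   one row per subject; an intercept is always added.
#' @return an object of class \code{partial_corr}: a list with
#'   \code{r_partial}, \code{r2}, \code{t_stat}, \code{df},
#'   \code{p_two_sided}, \code{n} and \code{k}.
#' @examples
#' set.seed(1)
#' cov <- matrix(rnorm(60), 20)
#' x <- rnorm(20); y <- -0.5 * x + rnorm(20)
#' partial_correlation(y, x, cov)
#' @export
partial_correlation <- function(y, x, covariates) {
  covariates <- as.matrix(covariates)
  n <- length(y)
  k <- ncol(covariates)
  if (length(x) != n || nrow(covariates) != n)
    stop("'y', 'x' and 'covariates' must have matching lengths")
  if (anyNA(y) || anyNA(x) || anyNA(covariates))
    stop("missing values are not allowed")
  if (n <= k + 2)
    stop(sprintf("need n > k + 2 (n = %d, k = %d)", n, k))
  X <- cbind(1, covariates)
  res <- ls_residuals(X, cbind(y, x))
  ey <- res[, 1]
  ex <- res[, 2]
  sy <- sqrt(sum(ey^2))
  sx <- sqrt(sum(ex^2))
  if (sy < 1e-12 * max(1, stats::sd(y)) || sx < 1e-12 * max(1, stats::sd(x)))
    stop("degenerate sample: a residual vector is constant after removing covariates")
  r <- sum(ey * ex) / (sy * sx)
  r <- max(-1, min(1, r))
  df <- n - 2L - k
  t_stat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(r_partial = r, r2 = r^2, t_stat = t_stat, df = df,
                 p_two_sided = p, n = n, k = k),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat("Partial correlation (", x$k, " covariates)\n", sep = "")
  cat(sprintf("  r = %.4f, R2 = %.4f, t(%d) = %.3f, p = %.3g\n",
              x$r_partial, x$r2, x$df, x$t_stat, x$p_two_sided))
  invisible(x)
}

#' Smallest squared partial correlation declared significant
#'
#' Converts the critical t value at significance level \code{alpha} into the
#' corresponding squared partial correlation,
#' \eqn{t_c^2 / (t_c^2 + df)} with \eqn{df = n - 2 - k}: the floor below
#' which no sample estimate can reach significance at that n.
#'
#' @param n sample size.
#' @param k number of covariates partialled out.
#' @param alpha significance level.
#' @param tails 1 or 2 (default two-sided).
#' @return the minimal significant R2 (a fraction).
#' @examples
#' critical_r2(30, 5, 0.05)   # ~0.16
#' critical_r2(90, 5, 0.05)   # ~0.05
#' @export
critical_r2 <- function(n, k, alpha, tails = 2) {
  stopifnot_scalar_prob(alpha, "alpha", open_upper = TRUE)
  if (alpha <= 0) stop("'alpha' must be in (0,1)")
  if (!tails %in% c(1, 2)) stop("'tails' must be 1 or 2")
  df <- n - 2 - k
  if (!is_scalar_number(df) || df < 1) stop("invalid degrees of freedom: need n - 2 - k >= 1")
  t_crit <- stats::qt(1 - alpha / tails, df)
  t_crit^2 / (t_crit^2 + df)
}

#' Analytic power of the partial-correlation test (Fisher-z approximation)
#'
#' Power of the two-sided test of zero partial correlation at level
#' \code{alpha} when the population squared partial correlation is
#' \code{rho2}, using the normal approximation on the Fisher-z scale with
#' standard error \eqn{1/\sqrt{n - k - 3}}.
#'
#' @param rho2 population squared partial correlation, in [0, 1).
#' @param n sample size.
#' @param k number of covariates.
#' @param alpha significance level (two-sided).
#' @return the rejection probability. Vectorised over \code{rho2}.
#' @examples
#' analytic_power(0.11, 30, 5, 0.05)   # ~0.37
#' analytic_power(0.11, 180, 5, 0.05)  # ~1
#' @export
analytic_power <- function(rho2, n, k, alpha) {
  stopifnot_scalar_prob(alpha, "alpha", open_upper = TRUE)
  if (any(rho2 < 0 | rho2 >= 1)) stop("'rho2' must be in [0, 1)")
  if (n <= k + 3) stop("need n > k + 3 for the Fisher-z approximation")
  zbar <- atanh(sqrt(rho2))
  se <- 1 / sqrt(n - k - 3)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(zbar / se - zc) + stats::pnorm(-zbar / se - zc)
}

#' Flat-prior credible interval for a squared partial correlation
#'
#' Equal-tailed credible interval for R2 under a flat prior, constructed on
#' the Fisher-z scale: the posterior of the partial correlation's z
#' transform is Normal with mean \code{atanh(sqrt(r2))} (carrying the
#' observed sign) and standard deviation \eqn{1/\sqrt{n - k - 3}}. The
#' interval is mapped back through \code{tanh} to the correlation scale and
#' squared. If the correlation interval straddles zero the lower R2 bound is
#' 0 and the upper bound is the larger of the two squared endpoints.
#'
#' @param r2 observed squared partial correlation, in [0, 1).
#' @param n sample size.
#' @param k number of covariates.
#' @param level credibility level (default 0.95).
#' @param sign sign of the observed partial correlation (+1 or -1); does not
#'   affect the R2 bounds, retained for reporting.
#' @return an object of class \code{credible_interval} with \code{lower_r2},
#'   \code{upper_r2}, \code{level} and \code{method}.
#' @examples
#' credible_interval_r2(0.11, 360, 5)  # (0.06, 0.18) at 2 decimals
#' @export
credible_interval_r2 <- function(r2, n, k, level = 0.95, sign = -1) {
  stopifnot_scalar_prob(level, "level", open_upper = TRUE)
  if (level <= 0) stop("'level' must be in (0,1)")
  if (!is_scalar_number(r2) || r2 < 0 || r2 >= 1) stop("'r2' must be in [0, 1)")
  if (n - k - 3 <= 0) stop("need n > k + 3")
  z <- atanh(sqrt(r2))
  se <- 1 / sqrt(n - k - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  r_bounds <- tanh(z + c(-1, 1) * q * se)
  if (r_bounds[1] < 0) {
    lower <- 0
    upper <- max(r_bounds^2)
  } else {
    lower <- r_bounds[1]^2
    upper <- r_bounds[2]^2
  }
  structure(list(lower_r2 = lower, upper_r2 = upper, level = level,
                 sign = sign, method = "fisher_z_flat_prior"),
            class = "credible_interval")
}

#' @export
print.credible_interval <- function(x, ...) {
  cat(sprintf("%d%% credible interval for R2 (flat prior, Fisher-z): [%.3f, %.3f]\n",
              round(100 * x$level), x$lower_r2, x$upper_r2))
  invisible(x)
}

#' Probability that the estimated partial correlation has the wrong sign
#'
#' Under the Fisher-z approximation, the probability that a sample partial
#' correlation comes out with the sign opposite to the population effect:
#' \eqn{\Phi(-\mathrm{atanh}(\sqrt{\rho^2})\sqrt{n - k - 3})}.
#'
#' @param rho2 population squared partial correlation (> 0 for a defined
#'   direction).
#' @param n sample size.
#' @param k number of covariates.
#' @return the sign-error probability; 0.5 with a warning when
#'   \code{rho2 = 0} (direction undefined).
#' @examples
#' sign_error_probability(0.11, 30, 5)  # ~0.05
#' @export
sign_error_probability <- function(rho2, n, k) {
  if (!is_scalar_number(rho2) || rho2 < 0 || rho2 >= 1) stop("'rho2' must be in [0, 1)")
  if (n - k - 3 <= 0) stop("need n > k + 3")
  if (rho2 == 0) {
    warning("rho2 = 0: effect direction undefined, returning 0.5")
    return(0.5)
  }
  stats::pnorm(-atanh(sqrt(rho2)) * sqrt(n - k - 3))
}
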