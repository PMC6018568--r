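# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer stream
#' identifiers so that each stage of a study (cohort generation, volume
#' synthesis, permutation nulls, each bootstrap stratum) consumes an
#' independent, reproducible RNG stream. The mix is done in split 20-bit
#' arithmetic so every intermediate stays exactly representable as a double.
#'
#' @param master integer master seed.
#' @param ... integer stream identifiers (at least one).
#' @return a single integer in \code{[1, 2^31 - 2]} suitable for
#'   \code{set.seed()}.
#' @export
derive_seed <- function(master, ...) {
  ids <- as.double(unlist(list(...)))
  if (length(ids) == 0L) stop("at least one stream identifier is required")
  x <- as.double(abs(as.integer(master))) %% 2147483647
  for (k in ids) {
    lo <- x %% 1048576
    hi <- x %/% 1048576
    x <- (lo * 2045 + hi * 154 + (k %% 1048576) * 7919 +
            (k %/% 1048576) * 104729 + 1) %% 2147483647
  }
  as.integer(x %% 2147483645 + 1)
}

# residuals of each column of y on the column space of X (with intercept
# already included in X); uses one QR shared across columns
ls_residuals <- function(X, y) {
  y <- as.matrix(y)
  qr.resid(qr(X), y)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_prob <- function(x, name, open_upper = FALSE) {
  if (!is_scalar_number(x) || x < 0 || x > 1 || (open_upper && x >= 1)) {
    stop(sprintf("'%s' must be a single number in [0, %s]", name,
                 if (open_upper) "1)" else "1"), call. = FALSE)
  }
  invisible(x)
}

# two-decimal display formatting used by the report tables; empty cells
# (no resamples in that stratum) render as an en dash
fmt2 <- function(x) {
  ifelse(is.na(x), "–", sprintf("%.2f", x))
}

# short stable polynomial hash of a character scalar, for provenance records
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
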