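# Synthesis of per-patient fuzzy and binary lesion volumes. Each patient's
# lesion is a single smooth blob: abnormality 1.0 inside a core radius,
# Gaussian decay outside it. The blob's size is chosen so the thresholded
# (binary) volume reproduces the patient's lesion size in cm^3, and its
# distance from the designated true ROI is chosen so the mean fuzzy value
# over the ROI reproduces the patient's latent lesion load (with a final
# in-ROI shift to nail the load to tolerance).

#' Construct a volume set
#'
#' A volume set holds one 3-D volume per patient as columns of a
#' voxels-by-patients matrix, plus the shared grid geometry. All
#' cross-patient operations in the package require a single shared grid.
#'
#' @param data numeric matrix, \code{prod(dim)} rows, one column per patient.
#' @param dim integer length-3 grid shape.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param patient_ids character vector of column identities.
#' @param kind "fuzzy" or "binary".
#' @return an object of class \code{volume_set}.
#' @export
volume_set <- function(data, dim, voxel_size_mm, patient_ids, kind = c("fuzzy", "binary")) {
  kind <- match.arg(kind)
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, nrow(data) == prod(dim),
            ncol(data) == length(patient_ids))
  structure(list(data = data, dim = dim, voxel_size_mm = voxel_size_mm,
                 patient_ids = as.character(patient_ids), kind = kind),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat(sprintf("<volume_set> %d %s volumes, grid %s at %.1f mm\n",
              ncol(x$data), x$kind, paste(x$dim, collapse = "x"), x$voxel_size_mm))
  invisible(x)
}

#' Extract one patient's volume as a 3-D array
#' @param vs a \code{\link{volume_set}}.
#' @param i patient index or id.
#' @return a 3-D numeric array.
#' @export
volume_array <- function(vs, i) {
  if (is.character(i)) i <- match(i, vs$patient_ids)
  array(vs$data[, i], dim = vs$dim)
}

#' Number of patients in a volume set
#' @param vs a \code{\link{volume_set}}.
#' @export
n_patients <- function(vs) ncol(vs$data)

roi_linear_indices <- function(true_roi, grid_shape) {
  if (any(true_roi < 1) ||
      any(true_roi[, 1] > grid_shape[1]) ||
      any(true_roi[, 2] > grid_shape[2]) ||
      any(true_roi[, 3] > grid_shape[3]))
    stop("true_roi contains voxel indices outside the grid")
  (true_roi[, 3] - 1L) * grid_shape[1] * grid_shape[2] +
    (true_roi[, 2] - 1L) * grid_shape[1] + true_roi[, 1]
}

#' Generate fuzzy and binary lesion volumes for a cohort
#'
#' For each patient, builds a smooth contiguous abnormality blob whose
#' thresholded extent matches the patient's lesion size and whose mean
#' fuzzy value over the configured true ROI matches the patient's latent
#' lesion load (within 0.01). A patient with latent load exactly zero gets
#' an empty (all-zero) volume — the degenerate null case.
#'
#' @param config a \code{\link{generator_config}} (grid, ROI, threshold).
#' @param cohort cohort data.frame with \code{lesion_size_cm3}.
#' @param lesion_load per-patient latent loads in [0, 1].
#' @param seed integer seed for blob placement (mandatory).
#' @param decay_width_mm Gaussian decay width of the blob edge (default 8).
#' @return list with elements \code{fuzzy} and \code{binary}, both
#'   \code{\link{volume_set}} objects.
#' @export
generate_lesion_volumes <- function(config, cohort, lesion_load,
                                    seed = derive_seed(config$seed, 303L),
                                    decay_width_mm = 8) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) stop("'seed' is mandatory")
  n <- nrow(cohort)
  stopifnot(length(lesion_load) == n)
  gs <- config$grid_shape
  h <- config$voxel_size_mm
  thr <- config$binary_threshold
  roi_idx <- roi_linear_indices(config$true_roi, gs)
  nvox <- prod(gs)
  voxvol <- h^3 / 1000   # cm^3

  # voxel-centre coordinates (mm) per axis
  cx <- (seq_len(gs[1]) - 0.5) * h
  cy <- (seq_len(gs[2]) - 0.5) * h
  cz <- (seq_len(gs[3]) - 0.5) * h
  roi_center <- c(mean(cx[config$true_roi[, 1]]),
                  mean(cy[config$true_roi[, 2]]),
                  mean(cz[config$true_roi[, 3]]))
  c_thr <- sqrt(2 * log(1 / thr))   # threshold crossing in decay widths

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  fuzzy <- matrix(0, nvox, n)
  binary <- matrix(0, nvox, n)

  blob <- function(center, r_core, w) {
    d2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, "+"),
                (cz - center[3])^2, "+")
    d <- sqrt(d2)
    v <- exp(-pmax(d - r_core, 0)^2 / (2 * w^2))
    v[d <= r_core] <- 1
    v
  }

  for (i in seq_len(n)) {
    load_i <- lesion_load[i]
    if (load_i <= 0) next
    target_count <- cohort$lesion_size_cm3[i] / voxvol
    r_bin <- (3 * cohort$lesion_size_cm3[i] * 1000 / (4 * pi))^(1 / 3)
    w_i <- min(decay_width_mm, 0.8 * r_bin / c_thr)
    r_core <- max(0, r_bin - c_thr * w_i)

    d_i <- if (load_i >= 1) 0 else r_core + w_i * sqrt(-2 * log(load_i))
    d_i <- min(d_i, 0.45 * min(gs * h))
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    center <- roi_center + d_i * u
    center <- pmin(pmax(center, h), gs * h - h)

    # iterate the blob radius so the discrete thresholded count matches the
    # target lesion size despite voxelisation and grid-edge truncation
    v <- blob(center, r_core, w_i)
    for (it in 1:4) {
      cnt <- sum(v >= thr)
      if (cnt == 0) {
        r_core <- r_core + h
      } else {
        ratio <- (target_count / cnt)^(1 / 3)
        if (abs(ratio - 1) < 0.02) break
        r_eff <- r_core + c_thr * w_i
        r_core <- max(0, r_eff * ratio - c_thr * w_i)
      }
      v <- blob(center, r_core, w_i)
    }

    # nail the ROI mean to the latent load with a clipped uniform shift
    v_roi <- v[roi_idx]
    for (it in 1:25) {
      delta <- load_i - mean(v_roi)
      if (abs(delta) < 1e-3) break
      v_roi <- pmin(1, pmax(0, v_roi + delta))
    }
    v[roi_idx] <- v_roi

    fuzzy[, i] <- v
    binary[, i] <- as.numeric(v >= thr)
  }

  fz <- volume_set(fuzzy, gs, h, cohort$patient_id, "fuzzy")
  bz <- volume_set(binary, gs, h, cohort$patient_id, "binary")

  if (n >= 90) {
    roi_overlap <- rowSums(binary[roi_idx, , drop = FALSE])
    if (min(roi_overlap) < 5)
      warning(sprintf("true-ROI overlap fell below 5 at %d voxel(s); the ROI may not be discoverable",
                      sum(roi_overlap < 5)))
  }
  list(fuzzy = fz, binary = bz)
}
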