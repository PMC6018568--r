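# NIfTI input/output for lesion volumes, plus overlap maps and the
# minimum-overlap analysis mask that restricts all voxel-wise inference.

#' Write a volume set to per-patient NIfTI files
#'
#' One file per patient, named \code{<patient_id>_<kind>.nii.gz}, all
#' sharing the grid and voxel size of the set.
#'
#' @param vs a \code{\link{volume_set}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_volumes <- function(vs, dir) {
  stopifnot(inherits(vs, "volume_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s.nii.gz", vs$patient_ids, vs$kind))
  for (i in seq_along(paths)) {
    img <- RNifti::asNifti(volume_array(vs, i))
    RNifti::pixdim(img) <- rep(vs$voxel_size_mm, 3)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Load a set of lesion volumes from NIfTI files
#'
#' Reads the files, checks that every image sits on the same grid with the
#' same voxel dimensions, and enforces the value invariants of the
#' requested kind: fuzzy values must lie in [0, 1], binary values in
#' \{0, 1\}. Violations are reported with the offending file name.
#'
#' @param paths character vector of NIfTI file paths.
#' @param kind "fuzzy" or "binary".
#' @param patient_ids optional ids; defaults to file names stripped of the
#'   \code{_<kind>.nii[.gz]} suffix.
#' @return a \code{\link{volume_set}}.
#' @export
load_volumes <- function(paths, kind = c("fuzzy", "binary"), patient_ids = NULL) {
  kind <- match.arg(kind)
  if (length(paths) == 0L) stop("no volume files given")
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("file not found: ", paste(missing_files, collapse = ", "))
  if (is.null(patient_ids))
    patient_ids <- sub(sprintf("_%s\\.nii(\\.gz)?$", kind), "",
                       basename(paths))
  ref_dim <- NULL
  ref_pix <- NULL
  data <- NULL
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    a <- as.array(img)
    if (length(dim(a)) != 3L)
      stop(sprintf("'%s' is not a 3-D volume", paths[i]))
    pix <- RNifti::pixdim(img)[1:3]
    if (is.null(ref_dim)) {
      ref_dim <- dim(a)
      ref_pix <- pix
      data <- matrix(0, prod(ref_dim), length(paths))
    } else if (!identical(dim(a), ref_dim) || max(abs(pix - ref_pix)) > 1e-6) {
      stop(sprintf("grid mismatch: '%s' does not match '%s'", paths[i], paths[1]))
    }
    if (kind == "fuzzy") {
      if (min(a) < 0 || max(a) > 1)
        stop(sprintf("fuzzy values outside [0,1] in '%s'", paths[i]))
    } else {
      if (!all(a %in% c(0, 1)))
        stop(sprintf("non-binary values in '%s'", paths[i]))
    }
    data[, i] <- as.vector(a)
  }
  volume_set(data, ref_dim, ref_pix[1], patient_ids, kind)
}

#' Build a lesion overlap map
#'
#' Voxel-wise count of patients whose binary lesion covers each voxel.
#'
#' @param binaries a binary \code{\link{volume_set}}.
#' @return an object of class \code{overlap_map}: list with \code{counts}
#'   (3-D integer array), \code{voxel_size_mm} and \code{n_patients}.
#' @export
build_overlap_map <- function(binaries) {
  stopifnot(inherits(binaries, "volume_set"))
  if (binaries$kind != "binary") stop("overlap maps are built from binary volumes")
  if (ncol(binaries$data) == 0L) stop("empty volume set")
  counts <- array(as.integer(rowSums(binaries$data)), dim = binaries$dim)
  structure(list(counts = counts, voxel_size_mm = binaries$voxel_size_mm,
                 n_patients = ncol(binaries$data)),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("<overlap_map> grid %s, n = %d patients, max overlap %d\n",
              paste(dim(x$counts), collapse = "x"), x$n_patients, max(x$counts)))
  invisible(x)
}

#' Threshold an overlap map into the analysis mask
#'
#' Keeps voxels damaged in at least \code{min_patients} patients; all
#' voxel-wise model fitting is restricted to this mask.
#'
#' @param overlap an \code{\link{overlap_map}}.
#' @param min_patients minimum overlap count (default 5).
#' @return an object of class \code{analysis_mask}: list with
#'   \code{in_mask} (3-D logical array) and \code{n_voxels}.
#' @export
make_analysis_mask <- function(overlap, min_patients = 5) {
  stopifnot(inherits(overlap, "overlap_map"))
  if (!is_scalar_number(min_patients) || min_patients < 1)
    stop("'min_patients' must be >= 1")
  in_mask <- overlap$counts >= min_patients
  nv <- sum(in_mask)
  if (nv == 0L) stop("no analyzable voxels: mask is empty at min_patients = ", min_patients)
  structure(list(in_mask = in_mask, n_voxels = nv,
                 min_patients = min_patients),
            class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %d voxels at min overlap %d\n",
              x$n_voxels, x$min_patients))
  invisible(x)
}

#' Write an overlap map or mask to NIfTI
#' @param x an \code{overlap_map} or \code{analysis_mask}.
#' @param path output file; masks are written as uint8.
#' @param voxel_size_mm voxel size, required for masks.
#' @return invisibly, \code{path}.
#' @export
write_map_nifti <- function(x, path, voxel_size_mm = NULL) {
  if (inherits(x, "overlap_map")) {
    arr <- x$counts
    vox <- x$voxel_size_mm
    dt <- "int16"
  } else if (inherits(x, "analysis_mask")) {
    arr <- array(as.integer(x$in_mask), dim = dim(x$in_mask))
    vox <- voxel_size_mm
    if (is.null(vox)) stop("'voxel_size_mm' is required when writing a mask")
    dt <- "uint8"
  } else stop("unsupported object")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vox, 3)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
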