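#' Construct a brain volume
#'
#' A volume is a 3-D real-valued grid together with its voxel size in mm
#' and a 4x4 voxel-to-world affine. The affine maps 0-based voxel indices
#' (homogeneous coordinates) to world mm coordinates; the default places
#' the world origin at the grid centre, so that rotations and scalings of
#' the registration model act about the centre of the field of view.
#'
#' By convention the first grid axis is the left-right axis: midplane
#' reflection flips it, and atlases must share the orientation and grid of
#' the volumes they parcellate (no reorientation logic is applied).
#'
#' @param data numeric 3-D array; all values must be finite.
#' @param voxel_size positive length-3 numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix, or `NULL` for the centred
#'   default `diag(voxel_size)` with a translation putting the origin at
#'   the grid centre.
#' @return An object of class `"mkl_volume"`.
#' @export
volume <- function(data, voxel_size = c(2, 2, 2), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (!all(is.finite(data)))
    stop("volume data must be finite (no NA/NaN/Inf)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dim(data) - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "mkl_volume")
}

#' @export
print.mkl_volume <- function(x, ...) {
  cat(sprintf("<mkl_volume> %s voxels, %s mm; range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.mkl_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "mkl_volume")

stopifnot_volume <- function(v) {
  if (!is_volume(v)) stop("expected an `mkl_volume` object")
  invisible(v)
}

#' Read a 3-D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [volume()] with data, voxel size and affine taken from the
#'   file header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), "-D image: ", path)
  volume(array(as.numeric(img), d),
         voxel_size = as.numeric(RNifti::pixdim(img))[1:3],
         affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as float32; the affine is written to both qform and
#' sform. Volumes containing non-finite values are rejected before any
#' file is touched.
#'
#' @param v an [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot_volume(v)
  if (!all(is.finite(v$data)))
    stop("refusing to write volume with non-finite values")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$voxel_size
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

gaussian_taps <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with the kernel width given as full width at
#' half maximum in mm; the per-axis sigma in voxels is
#' `fwhm_mm / (voxel_size * 2 * sqrt(2 * log(2)))`. Boundaries are handled
#' by reflection, which keeps the total intensity conserved to well within
#' 0.1%.
#'
#' @param v an [volume()].
#' @param fwhm_mm positive smoothing width in mm (FWHM).
#' @return The smoothed volume on the same grid.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot_volume(v)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("`fwhm_mm` must be a single positive number")
  sigma_vox <- fwhm_mm / (v$voxel_size * 2 * sqrt(2 * log(2)))
  kernels <- lapply(1:3, function(axis)
    if (sigma_vox[axis] < 1e-8) 1 else gaussian_taps(sigma_vox[axis]))
  out <- .conv3d_sep(as.numeric(v$data), dim(v$data), kernels)
  volume(array(out, dim(v$data)), v$voxel_size, v$affine)
}

#' Reflect a volume about the hemisphere midplane
#'
#' Flips the grid along the left-right axis (the first array axis by
#' convention), mapping voxel `(1, j, k)` to `(X, j, k)`. Applying the
#' reflection twice returns the original volume.
#'
#' @param v an [volume()].
#' @return The reflected volume.
#' @export
reflect_midplane <- function(v) {
  stopifnot_volume(v)
  d <- dim(v$data)
  volume(v$data[d[1]:1, , , drop = FALSE], v$voxel_size, v$affine)
}

#' Threshold-based brain mask
#'
#' Marks voxels whose intensity exceeds `frac` times the volume maximum.
#' This is the in-brain voxel population used for whole-brain features and
#' for intensity normalization.
#'
#' @param v an [volume()] with a positive maximum.
#' @param frac threshold fraction in (0, 1).
#' @return A logical array of the volume's shape.
#' @export
compute_brain_mask <- function(v, frac = 0.1) {
  stopifnot_volume(v)
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac >= 1)
    stop("`frac` must be a single number in (0, 1)")
  mx <- max(v$data)
  if (mx <= 0) stop("cannot mask a volume without positive intensities")
  v$data > frac * mx
}

#' Construct a label atlas
#'
#' An atlas is an integer label grid (0 = background) aligned to the
#' volumes it parcellates, plus a label-to-region-name lookup.
#'
#' @param labels integer 3-D array of nonnegative labels.
#' @param names character vector of region names, with the corresponding
#'   integer labels as element names (e.g. `c("1" = "putamen-L")`).
#' @param voxel_size,affine grid geometry, as for [volume()].
#' @return An object of class `"mkl_atlas"`.
#' @export
atlas <- function(labels, names, voxel_size = c(2, 2, 2), affine = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be nonnegative integers")
  lv <- sort(unique(labels[labels > 0L]))
  if (is.null(base::names(names)))
    stop("`names` must carry integer labels as element names")
  key <- as.integer(base::names(names))
  if (anyNA(key)) stop("`names` element names must be integer labels")
  if (!all(lv %in% key))
    stop("every nonzero label must appear in `names`; missing: ",
         paste(setdiff(lv, key), collapse = ", "))
  if (anyDuplicated(names)) stop("region names must be unique")
  geom <- volume(array(0, dim(labels)), voxel_size, affine)
  structure(list(labels = labels, names = names,
                 voxel_size = geom$voxel_size, affine = geom$affine),
            class = "mkl_atlas")
}

#' @export
print.mkl_atlas <- function(x, ...) {
  cat(sprintf("<mkl_atlas> %s voxels, %d regions\n",
              paste(dim(x$labels), collapse = "x"), length(x$names)))
  invisible(x)
}

#' Read an atlas (label NIfTI + two-column name table)
#'
#' @param label_path NIfTI-1 file of integer labels.
#' @param names_path whitespace-delimited two-column text file
#'   (label, region-name).
#' @return An [atlas()].
#' @export
read_atlas <- function(label_path, names_path) {
  v <- read_volume(label_path)
  lab <- round(v$data)
  if (max(abs(lab - v$data)) > 1e-3)
    stop("label volume contains non-integer values")
  tab <- read.table(names_path, header = FALSE, col.names = c("label", "name"),
                    colClasses = c("integer", "character"))
  nm <- tab$name
  names(nm) <- tab$label
  atlas(array(as.integer(lab), dim(lab)), nm, v$voxel_size, v$affine)
}

#' Write an atlas (label NIfTI + name table)
#'
#' @param a an [atlas()].
#' @param label_path,names_path output paths.
#' @return `label_path`, invisibly.
#' @export
write_atlas <- function(a, label_path, names_path) {
  if (!inherits(a, "mkl_atlas")) stop("expected an `mkl_atlas`")
  write_volume(volume(array(as.numeric(a$labels), dim(a$labels)),
                      a$voxel_size, a$affine), label_path)
  write.table(data.frame(label = names(a$names), name = unname(a$names)),
              names_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  invisible(label_path)
}
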