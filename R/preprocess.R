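#' 12-parameter affine transform parameters
#'
#' Parameter order follows the serialization convention
#' `tx ty tz rx ry rz sx sy sz hxy hxz hyz`: translations in mm,
#' rotations in radians, per-axis scales, and shears. The corresponding
#' world-coordinate matrix is `T %*% R %*% S %*% H` with
#' `R = Rx %*% Ry %*% Rz`; it acts about the world origin, which the
#' default volume affine places at the grid centre.
#'
#' @param tx,ty,tz translations (mm).
#' @param rx,ry,rz rotations about the x/y/z axes (radians).
#' @param sx,sy,sz strictly positive scales.
#' @param hxy,hxz,hyz shears.
#' @return A named numeric vector of length 12.
#' @export
affine_params <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
                          sx = 1, sy = 1, sz = 1,
                          hxy = 0, hxz = 0, hyz = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz,
         sx = sx, sy = sy, sz = sz, hxy = hxy, hxz = hxz, hyz = hyz)
  if (any(p[7:9] <= 0)) stop("scales must be strictly positive")
  p
}

#' Build the 4x4 world matrix of a parameter vector
#'
#' @param p a length-12 vector in [affine_params()] order.
#' @return An invertible 4x4 matrix.
#' @export
params_to_matrix <- function(p) {
  stopifnot(length(p) == 12L)
  cx <- cos(p[4]); sx_ <- sin(p[4])
  cy <- cos(p[5]); sy_ <- sin(p[5])
  cz <- cos(p[6]); sz_ <- sin(p[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx_), c(0, sx_, cx))
  Ry <- rbind(c(cy, 0, sy_), c(0, 1, 0), c(-sy_, 0, cy))
  Rz <- rbind(c(cz, -sz_, 0), c(sz_, cz, 0), c(0, 0, 1))
  S <- diag(p[7:9])
  H <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  M <- diag(4)
  M[1:3, 1:3] <- Rx %*% Ry %*% Rz %*% S %*% H
  M[1:3, 4] <- p[1:3]
  unname(M)
}

#' Apply an affine transform to a volume
#'
#' The transform describes the forward motion of the image content in
#' world coordinates; resampling pulls source intensities through the
#' inverse map with trilinear interpolation, writing onto the grid of
#' `target`. Voxels mapping outside the source get 0.
#'
#' @param v source [volume()].
#' @param params length-12 parameter vector, or a 4x4 world matrix.
#' @param target volume whose grid defines the output (defaults to `v`).
#' @return The resampled volume on the target grid.
#' @export
transform_volume <- function(v, params, target = v) {
  stopifnot_volume(v)
  stopifnot_volume(target)
  M <- if (is.matrix(params)) params else params_to_matrix(params)
  # output voxel (0-based) -> world -> inverse motion -> source voxel
  Mvox <- solve(v$affine) %*% solve(M) %*% target$affine
  out <- .affine_resample(as.numeric(v$data), dim(v$data),
                          dim(target$data), Mvox)
  volume(array(out, dim(target$data)), target$voxel_size, target$affine)
}

downsample_volume <- function(v, f) {
  if (f == 1) return(v)
  d <- dim(v$data)
  ix <- seq(1, d[1], by = f); iy <- seq(1, d[2], by = f)
  iz <- seq(1, d[3], by = f)
  aff <- v$affine %*% diag(c(f, f, f, 1))
  volume(v$data[ix, iy, iz, drop = FALSE], v$voxel_size * f, aff)
}

msd_cost <- function(p_active, active, p_full, src, ref) {
  p <- p_full
  p[active] <- p_active
  if (any(p[7:9] <= 0.1)) return(Inf)
  r <- transform_volume(src, p, ref)
  mean((r$data - ref$data)^2)
}

#' Affine registration by multi-resolution search
#'
#' Estimates the 12-parameter affine transform that minimizes the mean
#' squared intensity difference (MSD) between the transformed source and
#' the reference, using Nelder-Mead over a coarse-to-fine schedule: both
#' volumes are smoothed and decimated, and the degrees of freedom grow
#' from translations through rigid and scaled to the full affine model.
#' If the search fails to improve on the identity transform, the identity
#' is returned with `improved = FALSE` and a warning.
#'
#' @param source,reference [volume()]s on comparable grids.
#' @param opts list of options: `levels` (data frame of decimation
#'   `factor` and smoothing `fwhm` per level), `schedule` (data frame of
#'   `level`, `dof`, `maxit` stages), `parscale` (12 step scales).
#' @return A list with `params` (length-12), `volume` (source resampled
#'   onto the reference grid), `cost` (final full-resolution MSD) and
#'   `improved` (logical).
#' @export
affine_register <- function(source, reference, opts = list()) {
  stopifnot_volume(source)
  stopifnot_volume(reference)
  levels <- opts$levels %||% data.frame(factor = c(4, 2, 1),
                                        fwhm = c(8, 4, 0))
  schedule <- opts$schedule %||% data.frame(level = c(1, 1, 2, 3),
                                            dof = c(3, 6, 9, 12),
                                            maxit = c(200, 300, 300, 120))
  parscale <- opts$parscale %||% c(rep(2, 3), rep(0.05, 3),
                                   rep(0.02, 3), rep(0.02, 3))
  pyr_src <- list(); pyr_ref <- list()
  for (l in seq_len(nrow(levels))) {
    s <- source; r <- reference
    if (levels$fwhm[l] > 0) {
      s <- gaussian_smooth(s, levels$fwhm[l])
      r <- gaussian_smooth(r, levels$fwhm[l])
    }
    pyr_src[[l]] <- downsample_volume(s, levels$factor[l])
    pyr_ref[[l]] <- downsample_volume(r, levels$factor[l])
  }
  p <- affine_params()
  for (st in seq_len(nrow(schedule))) {
    l <- schedule$level[st]
    active <- seq_len(schedule$dof[st])
    fit <- optim(p[active], msd_cost, active = active, p_full = p,
                 src = pyr_src[[l]], ref = pyr_ref[[l]],
                 method = "Nelder-Mead",
                 control = list(maxit = schedule$maxit[st],
                                parscale = parscale[active],
                                reltol = 1e-8))
    p[active] <- fit$par
  }
  id <- affine_params()
  cost_id <- msd_cost(id, 1:12, id, source, reference)
  cost_p <- msd_cost(p, 1:12, p, source, reference)
  if (cost_p > cost_id) {
    warning("registration failed to improve over identity")
    return(list(params = id, volume = transform_volume(source, id, reference),
                cost = cost_id, improved = FALSE))
  }
  list(params = p, volume = transform_volume(source, p, reference),
       cost = cost_p, improved = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a symmetric template from a set of volumes
#'
#' All volumes are affinely registered to the one at `reference_index`;
#' the registered volumes and their hemisphere midplane reflections are
#' averaged and smoothed. A final symmetrization enforces exact
#' left-right symmetry (`template[x,,] == template[X+1-x,,]` bit-exactly,
#' up to the averaging of the two half-images).
#'
#' @param volumes nonempty list of [volume()]s.
#' @param reference_index index of the registration target.
#' @param fwhm_mm smoothing width applied to the averaged template.
#' @param opts registration options, see [affine_register()].
#' @return The template volume on the reference grid.
#' @export
build_template <- function(volumes, reference_index = 1, fwhm_mm = 8,
                           opts = list()) {
  if (length(volumes) == 0) stop("empty volume list")
  if (reference_index < 1 || reference_index > length(volumes))
    stop("invalid reference index")
  ref <- volumes[[reference_index]]
  acc <- array(0, dim(ref$data))
  for (i in seq_along(volumes)) {
    reg <- if (i == reference_index) ref
           else affine_register(volumes[[i]], ref, opts)$volume
    acc <- acc + reg$data + reflect_midplane(reg)$data
  }
  tpl <- volume(acc / (2 * length(volumes)), ref$voxel_size, ref$affine)
  if (fwhm_mm > 0) tpl <- gaussian_smooth(tpl, fwhm_mm)
  # exact symmetry despite floating-point order effects in the filter
  volume((tpl$data + reflect_midplane(tpl)$data) / 2,
         ref$voxel_size, ref$affine)
}

#' Spatially normalize a volume onto a template
#'
#' Registers the volume to the template and resamples it onto the
#' template grid.
#'
#' @param v an [volume()].
#' @param template template volume (see [build_template()]).
#' @param opts registration options, see [affine_register()].
#' @return The normalized volume on the template grid.
#' @export
spatially_normalize <- function(v, template, opts = list()) {
  affine_register(v, template, opts)$volume
}

#' Normalize intensities to the mean of the top fraction
#'
#' Divides the volume by `I_max`, the mean of the
#' `ceiling(top_frac * N)` largest intensities among the `N` considered
#' voxels (those inside `mask`, or all voxels when `mask` is `NULL`).
#' After normalization the mean of that same top set is exactly 1, and
#' the operation is invariant to any positive global rescaling of the
#' input.
#'
#' @param v an [volume()].
#' @param mask optional logical array selecting the voxel population.
#' @param top_frac fraction of voxels defining the top set.
#' @return The normalized volume.
#' @export
normalize_intensity <- function(v, mask = NULL, top_frac = 0.001) {
  stopifnot_volume(v)
  vals <- if (is.null(mask)) as.numeric(v$data) else {
    if (!any(mask)) stop("empty mask")
    v$data[mask]
  }
  m <- max(1L, ceiling(top_frac * length(vals)))
  imax <- mean(sort(vals, decreasing = TRUE)[seq_len(m)])
  if (imax <= 0) stop("top-intensity reference is not positive")
  volume(v$data / imax, v$voxel_size, v$affine)
}
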