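#' Voxel weight map of a linear whole-brain SVM
#'
#' Rearranges the absolute values of the primal weight vector back into
#' brain form. With `normalize = TRUE` the in-mask values are min-max
#' scaled to [0, 1]; a constant weight magnitude degenerates to an
#' all-zero map. Out-of-mask voxels are exactly 0.
#'
#' @param model an `"svm_fit"` trained on the linear kernel of
#'   `X_train`.
#' @param X_train whole-brain training feature matrix.
#' @param voxel_index linear grid indices of the feature columns (the
#'   in-mask voxels, in extraction order).
#' @param grid grid dimensions (length-3 integer) or an [volume()]
#'   supplying geometry for [weight_map_volume()].
#' @param normalize min-max normalize the in-mask magnitudes to [0, 1].
#' @param signed keep the signed weights instead of magnitudes.
#' @return An object of class `"weight_map"`: `data` (array), `index`,
#'   `normalized`, `signed`, and grid geometry.
#' @export
voxel_weight_map <- function(model, X_train, voxel_index, grid,
                             normalize = TRUE, signed = FALSE) {
  w <- weight_vector(model, X_train)
  if (length(w) != length(voxel_index))
    stop("voxel_index length must match the feature count")
  if (is_volume(grid)) {
    gd <- dim(grid$data); vs <- grid$voxel_size; aff <- grid$affine
  } else {
    gd <- as.integer(grid); vs <- c(1, 1, 1); aff <- NULL
    if (length(gd) != 3) stop("`grid` must be a 3-D dim vector or volume")
  }
  if (any(voxel_index < 1 | voxel_index > prod(gd)))
    stop("voxel_index outside the grid")
  vals <- if (signed) w else abs(w)
  if (normalize) {
    rng <- range(vals)
    vals <- if (diff(rng) <= 0) rep(0, length(vals))
            else (vals - rng[1]) / diff(rng)
  }
  arr <- array(0, gd)
  arr[voxel_index] <- vals
  structure(list(data = arr, index = voxel_index, normalized = normalize,
                 signed = signed, voxel_size = vs, affine = aff),
            class = "weight_map")
}

#' Convert a weight map to a volume (e.g. for NIfTI export)
#'
#' @param map a `"weight_map"`.
#' @return An [volume()].
#' @export
weight_map_volume <- function(map) {
  stopifnot(inherits(map, "weight_map"))
  volume(map$data, map$voxel_size, map$affine)
}

#' Mean voxel weight of one region
#'
#' The region importance is the arithmetic mean of the weight-map values
#' over the region's voxels that lie inside the feature mask.
#'
#' @param map a `"weight_map"`.
#' @param a an [atlas()] on the same grid.
#' @param region region name (see [region_labels()]).
#' @return A single numeric weight.
#' @export
region_weight <- function(map, a, region) {
  stopifnot(inherits(map, "weight_map"))
  if (!all(dim(map$data) == dim(a$labels)))
    stop("weight map and atlas grids do not match")
  idx <- intersect(region_voxel_indices(a, region), map$index)
  if (length(idx) == 0)
    stop("region has no voxels inside the feature mask: ", region)
  mean(map$data[idx])
}

#' Region importance scores for a set of regions
#'
#' @inheritParams region_weight
#' @param regions region names (default: all merged atlas regions).
#' @return Named numeric vector of region weights.
#' @export
region_weights <- function(map, a, regions = atlas_regions(a)) {
  vapply(regions, function(r) region_weight(map, a, r), numeric(1))
}

#' Select the top-k regions by importance
#'
#' Regions are ranked by descending weight; ties are broken
#' alphabetically for determinism.
#'
#' @param rw named numeric vector of region weights.
#' @param k number of regions to keep.
#' @return Character vector of `k` region names in rank order.
#' @export
select_top_regions <- function(rw, k = 5) {
  if (is.null(names(rw))) stop("region weights must be named")
  if (any(!is.finite(rw))) stop("region weights must be finite")
  if (k < 1 || k > length(rw))
    stop("k must be between 1 and the number of scored regions")
  names(rw)[order(-rw, names(rw))][seq_len(k)]
}

#' Write region weights as a two-column table
#'
#' @param rw named numeric vector of region weights.
#' @param path output path (tab-delimited, sorted descending).
#' @return `path`, invisibly.
#' @export
write_region_weights <- function(rw, path) {
  ord <- order(-rw, names(rw))
  write.table(data.frame(region = names(rw)[ord], weight = rw[ord]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
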