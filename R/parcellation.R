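#' Resolve the atlas labels of a named region
#'
#' A region name may be (i) an exact atlas entry (e.g. `"putamen-L"`),
#' (ii) a merged bilateral name covering the `-L`/`-R` pair (e.g.
#' `"putamen"`), or (iii) the convenience alias `"striatum"` for the
#' union of putamen and caudate.
#'
#' @param a an [atlas()].
#' @param region region name.
#' @return Integer vector of matching labels.
#' @export
region_labels <- function(a, region) {
  if (!inherits(a, "mkl_atlas")) stop("expected an `mkl_atlas`")
  nm <- a$names
  base <- sub("-(L|R)$", "", nm)
  labs <- if (region %in% nm) {
    names(nm)[nm == region]
  } else if (region %in% base) {
    names(nm)[base == region]
  } else if (region == "striatum") {
    names(nm)[base %in% c("putamen", "caudate")]
  } else {
    stop("unknown region: ", region)
  }
  if (length(labs) == 0) stop("unknown region: ", region)
  as.integer(labs)
}

#' Linear voxel indices of a region, in fixed grid order
#'
#' Ordering is ascending column-major linear index (first grid axis
#' fastest), which fixes the feature column order for every extraction.
#'
#' @inheritParams region_labels
#' @return Sorted integer vector of linear indices into the label grid.
#' @export
region_voxel_indices <- function(a, region) {
  idx <- which(a$labels %in% region_labels(a, region))
  if (length(idx) == 0) stop("region has no voxels in the atlas: ", region)
  idx
}

#' Merged region names of an atlas
#'
#' @param a an [atlas()].
#' @param merge_lr collapse `-L`/`-R` pairs into one bilateral name.
#' @return Character vector of region names (sorted, unique).
#' @export
atlas_regions <- function(a, merge_lr = TRUE) {
  if (!inherits(a, "mkl_atlas")) stop("expected an `mkl_atlas`")
  nm <- unname(a$names)
  if (merge_lr) nm <- sub("-(L|R)$", "", nm)
  sort(unique(nm))
}

#' Extract one region's voxel intensities
#'
#' @param v an [volume()] on the atlas grid.
#' @param a an [atlas()].
#' @param region region name (see [region_labels()]).
#' @return Numeric vector of in-region intensities in fixed grid order.
#' @export
extract_region_features <- function(v, a, region) {
  stopifnot_volume(v)
  if (!all(dim(v$data) == dim(a$labels)))
    stop("volume and atlas grids do not match")
  v$data[region_voxel_indices(a, region)]
}

#' Whole-brain voxel intensities
#'
#' @param v an [volume()].
#' @param mask logical array of in-brain voxels (see
#'   [compute_brain_mask()]).
#' @return Numeric vector of in-mask intensities in fixed grid order.
#' @export
whole_brain_features <- function(v, mask) {
  stopifnot_volume(v)
  if (!all(dim(v$data) == dim(mask)))
    stop("volume and mask grids do not match")
  if (!any(mask)) stop("empty mask")
  v$data[mask]
}

# rows = list elements, columns = feature vector entries; robust to
# single-voxel regions where vapply would drop the matrix dimension
stack_feature_rows <- function(lst, f, len) {
  m <- vapply(lst, f, numeric(len))
  if (is.matrix(m)) t(m) else matrix(m, ncol = 1)
}

#' Build per-(modality, region) feature blocks for a cohort
#'
#' One block per requested (modality, region) pair; by default the cross
#' product of `modalities` and `regions`. Rows follow the cohort's
#' subject order in every block; columns follow the fixed grid order of
#' [region_voxel_indices()].
#'
#' @param subjects a cohort (list of subject records).
#' @param a an [atlas()].
#' @param regions character vector of region names.
#' @param modalities character vector of modalities; every subject must
#'   carry each one.
#' @param pairs optional data frame with columns `modality` and `region`
#'   selecting explicit pairs instead of the cross product (used e.g. to
#'   append a single DaTSCAN striatum block to DMFP region blocks).
#' @return An object of class `"feature_set"`: list with `subject_ids`,
#'   `labels`, `blocks` (named matrices `"modality:region"`),
#'   `voxel_index` (per-block linear indices) and `grid_dim`.
#' @export
build_feature_sets <- function(subjects, a, regions, modalities = "dmfp",
                               pairs = NULL) {
  if (length(subjects) == 0) stop("empty cohort")
  if (is.null(pairs))
    pairs <- expand.grid(modality = modalities, region = regions,
                         stringsAsFactors = FALSE)
  ids <- cohort_ids(subjects)
  labels <- cohort_labels(subjects)
  blocks <- list(); voxel_index <- list()
  for (r in seq_len(nrow(pairs))) {
    m <- pairs$modality[r]; rg <- pairs$region[r]
    idx <- region_voxel_indices(a, rg)
    mat <- stack_feature_rows(subjects, function(s) {
      if (is.null(s$volumes[[m]]))
        stop("subject ", s$id, " lacks modality: ", m)
      extract_region_features(s$volumes[[m]], a, rg)
    }, length(idx))
    rownames(mat) <- ids
    if (any(!is.finite(mat))) stop("non-finite features in block ", m, ":", rg)
    key <- paste(m, rg, sep = ":")
    blocks[[key]] <- mat
    voxel_index[[key]] <- idx
  }
  structure(list(subject_ids = ids, labels = labels, blocks = blocks,
                 voxel_index = voxel_index, grid_dim = dim(a$labels)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d subjects, %d blocks\n",
              length(x$subject_ids), length(x$blocks)))
  for (b in names(x$blocks))
    cat(sprintf("  %s: %d voxels\n", b, ncol(x$blocks[[b]])))
  invisible(x)
}

#' Cache a feature set on disk
#'
#' Writes a little-endian float64 binary container plus a JSON sidecar
#' describing subject order, labels, block names/shapes and voxel
#' indices.
#'
#' @param fs a [build_feature_sets()] result.
#' @param prefix path prefix; `<prefix>.bin` and `<prefix>.json` are
#'   written.
#' @return `prefix`, invisibly.
#' @export
save_feature_set <- function(fs, prefix) {
  stopifnot(inherits(fs, "feature_set"))
  meta <- list(subject_ids = fs$subject_ids, labels = fs$labels,
               blocks = lapply(fs$blocks, dim),
               voxel_index = fs$voxel_index, grid_dim = fs$grid_dim)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = FALSE,
                       digits = NA)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (b in names(fs$blocks))
    writeBin(as.numeric(fs$blocks[[b]]), con, size = 8, endian = "little")
  invisible(prefix)
}

#' Load a cached feature set
#'
#' @param prefix prefix used with [save_feature_set()].
#' @return The reconstituted `"feature_set"`.
#' @export
load_feature_set <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  blocks <- list()
  for (b in names(meta$blocks)) {
    d <- as.integer(meta$blocks[[b]])
    mat <- matrix(readBin(con, "numeric", n = prod(d), size = 8,
                          endian = "little"), d[1], d[2])
    rownames(mat) <- meta$subject_ids
    blocks[[b]] <- mat
  }
  structure(list(subject_ids = meta$subject_ids, labels = meta$labels,
                 blocks = blocks,
                 voxel_index = lapply(meta$voxel_index, as.integer),
                 grid_dim = as.integer(meta$grid_dim)),
            class = "feature_set")
}
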