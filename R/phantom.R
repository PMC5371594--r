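#' Phantom cohort specification
#'
#' Defines the geometry and statistical model of a synthetic PET-like
#' cohort: a grid, an ellipsoidal "brain" of background tissue, a table of
#' spherical regions with per-modality baseline uptake, multiplicative
#' group effects on regional uptake, and a noise model. The defaults
#' emulate the structure of a striatal dopamine-receptor study: three
#' diagnostic groups (PD, MSA, PSP), striatal regions (putamen, caudate)
#' with roughly 10x the extrastriatal baseline, weaker but informative
#' signal in thalamus, olfactory region and supplementary motor area, and
#' uninformative filler regions. The `datscan` modality concentrates
#' essentially all signal in the striatum.
#'
#' Group effects are multiplicative uptake factors applied to regional
#' baselines: values below 1 model reduced tracer binding in that group.
#' Noise is i.i.d. Gaussian added within the brain before smoothing, so
#' the final images carry spatially correlated noise; an optional
#' per-subject global scale factor (log-normal, `subject_scale_sd`)
#' models uptake variability between subjects.
#'
#' @param shape grid dimensions (voxels).
#' @param voxel_size voxel edge lengths in mm.
#' @param regions data frame with columns `name`, `cx`, `cy`, `cz`
#'   (1-based voxel coordinates of the sphere centre), `radius_mm`, and
#'   one baseline-intensity column per modality (`dmfp`, `datscan`).
#' @param tissue_baseline named numeric, per-modality baseline of
#'   non-region brain tissue.
#' @param brain_semiaxes ellipsoid semi-axes of the brain, in voxels.
#' @param groups diagnostic group labels.
#' @param group_effects data frame with columns `group`, `region`
#'   (merged region name, e.g. `"putamen"` covers `putamen-L/R`) and
#'   `factor` (multiplicative uptake effect); pairs not listed default
#'   to 1.
#' @param noise_sd standard deviation of the voxel noise added before
#'   smoothing (intensity units).
#' @param smooth_fwhm_mm FWHM of the final smoothing applied to each
#'   simulated subject, in mm.
#' @param subject_scale_sd standard deviation of the per-subject
#'   log-normal global uptake factor (0 disables it).
#' @param modalities modalities to simulate.
#' @param seed default master seed for cohort simulation.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(40L, 48L, 34L),
                         voxel_size = c(2, 2, 2),
                         regions = default_phantom_regions(),
                         tissue_baseline = c(dmfp = 1, datscan = 0.15),
                         brain_semiaxes = c(16, 20, 14),
                         groups = c("PD", "MSA", "PSP"),
                         group_effects = default_group_effects(),
                         noise_sd = 1,
                         smooth_fwhm_mm = 6,
                         subject_scale_sd = 0,
                         modalities = "dmfp",
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            is.data.frame(regions), nrow(regions) >= 1,
            all(c("name", "cx", "cy", "cz", "radius_mm") %in% names(regions)),
            noise_sd >= 0, smooth_fwhm_mm >= 0, subject_scale_sd >= 0)
  if (anyDuplicated(regions$name)) stop("region names must be unique")
  for (m in modalities) {
    if (!m %in% names(regions))
      stop("regions table lacks a baseline column for modality: ", m)
    if (any(regions[[m]] <= 0))
      stop("baseline intensities must be positive (modality ", m, ")")
    if (!m %in% names(tissue_baseline))
      stop("tissue_baseline lacks modality: ", m)
  }
  if (!all(group_effects$group %in% groups))
    stop("group_effects refers to unknown groups")
  if (any(group_effects$factor <= 0))
    stop("group effect factors must be positive")
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 regions = regions, tissue_baseline = tissue_baseline,
                 brain_semiaxes = brain_semiaxes, groups = groups,
                 group_effects = group_effects, noise_sd = noise_sd,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 subject_scale_sd = subject_scale_sd,
                 modalities = modalities, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom region geometry
#'
#' Spherical regions on the default 40x48x34 grid (2 mm voxels):
#' paired putamen and caudate, midline thalamus, olfactory region and
#' supplementary motor area, plus four uninformative filler regions.
#' Striatal baselines are roughly 10x the extrastriatal ones; the
#' `datscan` column leaves near-zero signal outside the striatum.
#'
#' @return A data frame suitable for [phantom_spec()]'s `regions`.
#' @export
default_phantom_regions <- function() {
  data.frame(
    name = c("putamen-L", "putamen-R", "caudate-L", "caudate-R",
             "thalamus", "olfactory", "supplementary-motor-area",
             "frontal-filler", "occipital-filler",
             "temporal-filler-L", "temporal-filler-R"),
    cx = c(13, 28, 16, 25, 20.5, 20.5, 20.5, 20.5, 20.5, 9, 32),
    cy = c(26, 26, 32, 32, 22, 38, 29, 40, 10, 22, 22),
    cz = c(17, 17, 20, 20, 17, 10, 28, 20, 17, 12, 12),
    radius_mm = c(7, 7, 6, 6, 7, 5, 6, 5, 6, 5, 5),
    dmfp = c(10, 10, 9, 9, 2, 1.6, 1.5, 1.4, 1.3, 1.2, 1.2),
    datscan = c(10, 10, 9, 9, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2),
    stringsAsFactors = FALSE)
}

#' Default group uptake effects
#'
#' Multiplicative regional uptake factors distinguishing the groups: the
#' atypical syndromes (MSA, PSP) carry reduced post-synaptic striatal and
#' thalamic binding, while the idiopathic group carries reduced olfactory
#' and supplementary-motor uptake. Filler regions are unaffected.
#'
#' @return A data frame suitable for [phantom_spec()]'s `group_effects`.
#' @export
default_group_effects <- function() {
  data.frame(
    group = c("PD", "PD",
              "MSA", "MSA", "MSA",
              "PSP", "PSP", "PSP"),
    region = c("olfactory", "supplementary-motor-area",
               "putamen", "caudate", "thalamus",
               "putamen", "caudate", "thalamus"),
    factor = c(0.65, 0.80,
               0.65, 0.75, 0.80,
               0.70, 0.70, 0.75),
    stringsAsFactors = FALSE)
}

sphere_mask <- function(shape, voxel_size, centre, radius_mm) {
  cx <- (seq_len(shape[1]) - centre[1]) * voxel_size[1]
  cy <- (seq_len(shape[2]) - centre[2]) * voxel_size[2]
  cz <- (seq_len(shape[3]) - centre[3]) * voxel_size[3]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  d2 <= radius_mm^2
}

ellipsoid_mask <- function(shape, semiaxes) {
  centre <- (shape + 1) / 2
  cx <- ((seq_len(shape[1]) - centre[1]) / semiaxes[1])^2
  cy <- ((seq_len(shape[2]) - centre[2]) / semiaxes[2])^2
  cz <- ((seq_len(shape[3]) - centre[3]) / semiaxes[3])^2
  outer(outer(cx, cy, `+`), cz, `+`) <= 1
}

#' Build the toy label atlas of a phantom specification
#'
#' Paints each spherical region of the spec into an integer label grid
#' (labels 1..R in table order). Deterministic; overlapping region
#' definitions are an error.
#'
#' @param spec a [phantom_spec()].
#' @return An [atlas()] aligned to the phantom grid.
#' @export
make_toy_atlas <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- array(0L, spec$shape)
  for (r in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[r, ]
    m <- sphere_mask(spec$shape, spec$voxel_size,
                     c(rg$cx, rg$cy, rg$cz), rg$radius_mm)
    if (!any(m))
      stop("region does not fit inside the grid: ", rg$name)
    if (any(lab[m] != 0L))
      stop("overlapping region definitions: ", rg$name)
    lab[m] <- r
  }
  nm <- spec$regions$name
  names(nm) <- seq_len(nrow(spec$regions))
  atlas(lab, nm, spec$voxel_size)
}

effect_factor <- function(spec, group, region_name) {
  base <- sub("-(L|R)$", "", region_name)
  ge <- spec$group_effects
  hit <- ge$group == group & (ge$region == region_name | ge$region == base)
  if (any(hit)) ge$factor[which(hit)[1]] else 1
}

baseline_map <- function(spec, atlas, modality, group = NULL) {
  base <- array(0, spec$shape)
  base[ellipsoid_mask(spec$shape, spec$brain_semiaxes)] <-
    spec$tissue_baseline[[modality]]
  for (r in seq_len(nrow(spec$regions))) {
    f <- if (is.null(group)) 1 else effect_factor(spec, group,
                                                  spec$regions$name[r])
    base[atlas$labels == r] <- spec$regions[[modality]][r] * f
  }
  base
}

#' Simulate one phantom subject volume
#'
#' The intensity model is `baseline(region) * effect(group, region)`
#' inside regions and the tissue baseline elsewhere in the brain, plus
#' i.i.d. Gaussian voxel noise inside the brain, optionally scaled by a
#' per-subject log-normal uptake factor (off by default: the phantom
#' emulates volumes whose global scale has already been removed by
#' intensity normalization), and finally Gaussian smoothed. With
#' `noise_sd = 0` and unit effects, the result is exactly the smoothed
#' baseline map.
#'
#' @param atlas the phantom's [make_toy_atlas()] output.
#' @param spec a [phantom_spec()].
#' @param group diagnosis label; must be one of `spec$groups`.
#' @param seed integer seed for this subject's noise realization.
#' @param modality which baseline column to use.
#' @return An [volume()].
#' @export
simulate_subject <- function(atlas, spec, group, seed, modality = "dmfp") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!group %in% spec$groups)
    stop("unknown group: ", group)
  if (!modality %in% spec$modalities && !modality %in% names(spec$regions))
    stop("unknown modality: ", modality)
  set.seed(seed)
  signal <- baseline_map(spec, atlas, modality, group)
  scale <- if (spec$subject_scale_sd > 0)
    exp(rnorm(1, 0, spec$subject_scale_sd)) else 1
  dat <- signal * scale
  if (spec$noise_sd > 0) {
    inside <- signal > 0
    dat[inside] <- dat[inside] + rnorm(sum(inside), 0, spec$noise_sd)
  }
  v <- volume(dat, spec$voxel_size)
  if (spec$smooth_fwhm_mm > 0) v <- gaussian_smooth(v, spec$smooth_fwhm_mm)
  v
}

#' Simulate a labelled phantom cohort
#'
#' Per-subject seeds are derived deterministically from the master seed,
#' so the cohort is a pure function of `(spec, n_per_group, seed)`. The
#' default counts mirror a 39/24/24 PD/MSA/PSP cohort.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_group named integer vector of group sizes.
#' @param seed master seed (defaults to `spec$seed`).
#' @param atlas optionally a pre-built atlas (rebuilt from `spec` if
#'   omitted).
#' @param modalities modalities to simulate per subject.
#' @return A list of subject records, each a list with elements `id`,
#'   `diagnosis` and `volumes` (named list of [volume()]s).
#' @export
simulate_cohort <- function(spec,
                            n_per_group = c(PD = 39, MSA = 24, PSP = 24),
                            seed = spec$seed, atlas = NULL,
                            modalities = spec$modalities) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(n_per_group) == 0) stop("empty group list")
  if (any(n_per_group < 1)) stop("group counts must be >= 1")
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% spec$groups))
    stop("n_per_group must be named by groups of the spec")
  if (is.null(atlas)) atlas <- make_toy_atlas(spec)
  total <- sum(n_per_group)
  set.seed(seed)
  subj_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  total * length(modalities)),
                       nrow = total)
  subjects <- vector("list", total)
  i <- 0L
  for (g in names(n_per_group)) {
    for (s in seq_len(n_per_group[[g]])) {
      i <- i + 1L
      vols <- list()
      for (mi in seq_along(modalities))
        vols[[modalities[mi]]] <-
          simulate_subject(atlas, spec, g, subj_seeds[i, mi],
                           modality = modalities[mi])
      subjects[[i]] <- list(id = sprintf("%s-%03d", g, s),
                            diagnosis = g, volumes = vols)
    }
  }
  subjects
}

#' Diagnosis labels of a cohort
#' @param subjects a cohort from [simulate_cohort()] or [read_cohort()].
#' @return Character vector of diagnoses, in subject order.
#' @export
cohort_labels <- function(subjects)
  vapply(subjects, `[[`, character(1), "diagnosis")

#' Subject ids of a cohort
#' @inheritParams cohort_labels
#' @return Character vector of ids, in subject order.
#' @export
cohort_ids <- function(subjects)
  vapply(subjects, `[[`, character(1), "id")

#' Perturb a volume by a random affine transform
#'
#' Draws a random rigid-plus-scale perturbation (translations, rotations
#' and log-scales uniform within the stated bounds, shears zero), applies
#' it to the volume by trilinear resampling, and returns both the
#' perturbed volume and the true 12-parameter vector, for registration
#' recovery testing.
#'
#' @param v an [volume()].
#' @param max_shift_mm,max_rot_deg nonnegative bounds on translations and
#'   rotations.
#' @param seed optional seed.
#' @param max_log_scale bound on per-axis log scale factors.
#' @return A list with elements `volume` and `params` (see
#'   [affine_params()]).
#' @export
apply_random_affine <- function(v, max_shift_mm, max_rot_deg, seed = NULL,
                                max_log_scale = 0.02) {
  stopifnot_volume(v)
  if (max_shift_mm < 0 || max_rot_deg < 0)
    stop("perturbation bounds must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  p <- affine_params(
    tx = runif(1, -max_shift_mm, max_shift_mm),
    ty = runif(1, -max_shift_mm, max_shift_mm),
    tz = runif(1, -max_shift_mm, max_shift_mm),
    rx = runif(1, -max_rot_deg, max_rot_deg) * pi / 180,
    ry = runif(1, -max_rot_deg, max_rot_deg) * pi / 180,
    rz = runif(1, -max_rot_deg, max_rot_deg) * pi / 180,
    sx = exp(runif(1, -max_log_scale, max_log_scale)),
    sy = exp(runif(1, -max_log_scale, max_log_scale)),
    sz = exp(runif(1, -max_log_scale, max_log_scale)))
  list(volume = transform_volume(v, p), params = p)
}

#' Write a cohort as NIfTI files plus a manifest
#'
#' @param subjects a cohort.
#' @param dir output directory (created if needed).
#' @return Path of the written tab-delimited manifest (columns: id,
#'   diagnosis, one path column per modality), invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  modalities <- names(subjects[[1]]$volumes)
  rows <- lapply(subjects, function(s) {
    paths <- vapply(modalities, function(m) {
      fn <- sprintf("%s_%s.nii.gz", s$id, m)
      write_volume(s$volumes[[m]], file.path(dir, fn))
      fn
    }, character(1))
    c(id = s$id, diagnosis = s$diagnosis, paths)
  })
  man <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.tsv")
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest and its volumes
#'
#' @param manifest_path path to a manifest written by [write_cohort()]
#'   (volume paths are resolved relative to the manifest's directory).
#' @return A cohort (list of subject records).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- read.table(manifest_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("id", "diagnosis") %in% names(man)))
    stop("manifest must have `id` and `diagnosis` columns")
  modalities <- setdiff(names(man), c("id", "diagnosis"))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    vols <- lapply(modalities, function(m)
      read_volume(file.path(base, man[[m]][i])))
    names(vols) <- modalities
    list(id = man$id[i], diagnosis = man$diagnosis[i], volumes = vols)
  })
}
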