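#' Default pipeline configuration
#'
#' Defaults follow the evaluation protocol of the method: 10 outer
#' folds, top-5 region selection, C grid `2^e` for `e` in -3..5, kernel
#' weight lattice step 0.1, 5 inner folds for the grid search, and 1000
#' permutations for significance testing.
#'
#' @return A named list of configuration values (class `"run_config"`).
#' @export
default_config <- function() {
  structure(list(
    mode = "binary",            # binary | multiclass | multimodal
    modality = "dmfp",
    idiopathic_class = "PD",
    positive_name = "atypical", # pooled MSA+PSP class name
    k = 10L,
    inner_k = 5L,
    top_k = 5L,
    C_exponents = -3:5,
    q_step = 0.1,
    wb_C = 1,
    mask_frac = 0.1,
    n_perm = 1000L,
    seed = 1L,
    regions = NULL,             # NULL = all merged atlas regions
    extra_blocks = list(),      # e.g. list(list(modality="datscan", region="striatum"))
    paths = list()
  ), class = "run_config")
}

config_errors <- function(config) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(config$mode %in% c("binary", "multiclass", "multimodal"),
      "`mode` must be one of binary, multiclass, multimodal")
  chk(is.numeric(config$k) && config$k >= 2, "`k` must be at least 2")
  chk(is.numeric(config$inner_k) && config$inner_k >= 2,
      "`inner_k` must be at least 2")
  chk(is.numeric(config$top_k) && config$top_k >= 1,
      "`top_k` must be at least 1")
  chk(is.numeric(config$C_exponents) && length(config$C_exponents) >= 1,
      "`C_exponents` must be a numeric vector")
  chk(is.numeric(config$q_step) && config$q_step > 0 &&
        abs(round(1 / config$q_step) * config$q_step - 1) < 1e-9,
      "`q_step` must be positive and divide 1")
  chk(is.numeric(config$wb_C) && config$wb_C > 0,
      "`wb_C` must be positive")
  chk(is.numeric(config$mask_frac) && config$mask_frac > 0 &&
        config$mask_frac < 1,
      "`mask_frac` must be in (0, 1)")
  chk(is.numeric(config$n_perm) && config$n_perm >= 1,
      "`n_perm` must be at least 1")
  chk(is.numeric(config$seed), "`seed` must be numeric")
  chk(is.character(config$modality) && length(config$modality) == 1,
      "`modality` must be a single string")
  if (config$mode == "multimodal")
    chk(length(config$extra_blocks) >= 1,
        "multimodal mode needs at least one entry in `extra_blocks`")
  errs
}

#' Merge a partial configuration with the defaults and validate
#'
#' @param config named list of overrides (possibly already complete).
#' @return A validated complete `"run_config"`.
#' @export
merge_config <- function(config = list()) {
  base <- default_config()
  for (nm in names(config)) base[nm] <- list(config[[nm]])  # keeps NULLs
  unknown <- setdiff(names(config),
                     c(names(default_config()), "phantom"))
  errs <- config_errors(base)
  if (length(unknown))
    errs <- c(errs, paste0("unknown field(s): ",
                           paste(unknown, collapse = ", ")))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  base$k <- as.integer(base$k); base$inner_k <- as.integer(base$inner_k)
  base$top_k <- as.integer(base$top_k)
  base$n_perm <- as.integer(base$n_perm); base$seed <- as.integer(base$seed)
  if (!is.null(config$phantom)) base$phantom <- config$phantom
  class(base) <- "run_config"
  base
}

#' Load a run configuration from YAML
#'
#' Missing fields take the documented defaults; all schema violations
#' are reported together, not first-failure. The optional `phantom`
#' block carries overrides for [phantom_spec()] used by the `simulate`
#' subcommand.
#'
#' @param path YAML file.
#' @return A validated `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  merge_config(raw)
}

#' Write a run configuration as YAML
#'
#' @param config a `"run_config"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build a phantom specification from a configuration
#'
#' Applies the `phantom` block of the config as overrides on
#' [phantom_spec()] defaults; the `n_per_group` entry (default
#' 39/24/24) is returned alongside.
#'
#' @param config a `"run_config"`.
#' @return List with `spec` and `n_per_group`.
#' @export
phantom_from_config <- function(config) {
  ph <- config$phantom %||% list()
  n_per_group <- ph$n_per_group %||% c(PD = 39, MSA = 24, PSP = 24)
  if (!is.null(names(n_per_group))) n_per_group <- unlist(n_per_group)
  ph$n_per_group <- NULL
  args <- ph[names(ph) %in% names(formals(phantom_spec))]
  spec <- do.call(phantom_spec, args)
  list(spec = spec, n_per_group = n_per_group)
}
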