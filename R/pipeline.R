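#' Precompute the feature and kernel cache for the CV pipeline
#'
#' Extracts, once, everything the cross-validation loop needs: the
#' label-free brain mask (from the cohort mean image), the whole-brain
#' feature matrix and its kernel, per-candidate-region feature blocks
#' and kernels, the mapping of region voxels into whole-brain feature
#' columns, and any extra-modality blocks (e.g. a DaTSCAN striatum
#' kernel for the multimodal mode). Train/test subsetting then reduces
#' to indexing these matrices, so permutation re-runs stay cheap while
#' every fold still performs its own selection and tuning.
#'
#' @param subjects a cohort.
#' @param a an [atlas()] aligned to the volumes.
#' @param config a pipeline configuration, see [default_config()].
#' @return A cache list consumed by [run_cv_features()].
#' @export
prepare_cv_data <- function(subjects, a, config = default_config()) {
  config <- merge_config(config)
  modality <- config$modality
  vols <- lapply(subjects, function(s) {
    v <- s$volumes[[modality]]
    if (is.null(v)) stop("subject ", s$id, " lacks modality: ", modality)
    v
  })
  gd <- dim(vols[[1]]$data)
  mean_vol <- volume(Reduce(`+`, lapply(vols, `[[`, "data")) / length(vols),
                     vols[[1]]$voxel_size, vols[[1]]$affine)
  mask <- compute_brain_mask(mean_vol, config$mask_frac)
  wb_idx <- which(mask)
  X_wb <- stack_feature_rows(vols, function(v) v$data[wb_idx],
                             length(wb_idx))
  regions <- config$regions %||% atlas_regions(a)
  region_idx <- lapply(regions, function(r) region_voxel_indices(a, r))
  names(region_idx) <- regions
  in_mask <- vapply(region_idx, function(ix) sum(ix %in% wb_idx) > 0,
                    logical(1))
  if (!all(in_mask)) {
    warning("dropping regions outside the brain mask: ",
            paste(regions[!in_mask], collapse = ", "))
    regions <- regions[in_mask]
    region_idx <- region_idx[in_mask]
  }
  X_regions <- lapply(region_idx, function(ix)
    stack_feature_rows(vols, function(v) v$data[ix], length(ix)))
  K_regions <- lapply(X_regions, tcrossprod)
  wb_cols <- lapply(region_idx, function(ix) match(intersect(ix, wb_idx),
                                                   wb_idx))
  # selection only needs |w| at candidate-region voxels; restricting the
  # weight computation to those columns keeps permutation re-runs cheap
  sel_cols <- sort(unique(unlist(wb_cols)))
  X_wb_sel <- X_wb[, sel_cols, drop = FALSE]
  wb_cols_sel <- lapply(wb_cols, function(cols) match(cols, sel_cols))
  extra <- list()
  for (eb in config$extra_blocks) {
    key <- paste(eb$modality, eb$region, sep = ":")
    ix <- region_voxel_indices(a, eb$region)
    Xe <- stack_feature_rows(subjects, function(s) {
      v <- s$volumes[[eb$modality]]
      if (is.null(v)) stop("subject ", s$id, " lacks modality: ",
                           eb$modality)
      v$data[ix]
    }, length(ix))
    extra[[key]] <- list(X = Xe, K = tcrossprod(Xe))
  }
  list(ids = cohort_ids(subjects), labels = cohort_labels(subjects),
       mask = mask, wb_idx = wb_idx, X_wb = X_wb, K_wb = tcrossprod(X_wb),
       regions = regions, X_regions = X_regions, K_regions = K_regions,
       wb_cols = wb_cols, X_wb_sel = X_wb_sel, wb_cols_sel = wb_cols_sel,
       extra = extra, grid_dim = gd, config = config)
}

select_regions_fold <- function(cache, tr, y_tr, config) {
  wb_fit <- train_svm(cache$K_wb[tr, tr, drop = FALSE], y_tr, config$wb_C)
  coef_full <- numeric(nrow(cache$X_wb_sel))
  coef_full[tr] <- wb_fit$coef
  w <- abs(drop(crossprod(cache$X_wb_sel, coef_full)))
  rw <- vapply(cache$wb_cols_sel, function(cols) mean(w[cols]), numeric(1))
  select_top_regions(rw, config$top_k)
}

fit_fold_binary <- function(cache, tr, y_tr, config, fold_seed) {
  top <- select_regions_fold(cache, tr, y_tr, config)
  kernels <- lapply(cache$K_regions[top],
                    function(K) K[tr, tr, drop = FALSE])
  keys <- top
  for (key in names(cache$extra)) {
    kernels <- c(kernels, list(cache$extra[[key]]$K[tr, tr, drop = FALSE]))
    keys <- c(keys, key)
  }
  gs <- grid_search(kernels, y_tr, C_grid = 2^config$C_exponents,
                    q_step = config$q_step, inner_k = config$inner_k,
                    seed = fold_seed)
  K_full <- lapply(keys, function(key) {
    if (key %in% cache$regions) cache$K_regions[[key]]
    else cache$extra[[key]]$K
  })
  Ktr <- combine_kernels(lapply(K_full, function(K)
    K[tr, tr, drop = FALSE]), gs$q)
  fit <- train_svm(Ktr, y_tr, gs$C)
  list(fit = fit, regions = top, keys = keys, C = gs$C, q = gs$q,
       K_full = K_full)
}

fold_decision <- function(ffit, tr, te) {
  Kte <- combine_kernels(lapply(ffit$K_full, function(K)
    K[te, tr, drop = FALSE]), ffit$q)
  decision_values(ffit$fit, Kte)
}

#' Run the cross-validated MKL pipeline on a prepared cache
#'
#' Per outer fold: (a) train a whole-brain linear SVM on the training
#' subjects only; (b) rank regions by mean absolute voxel weight and
#' keep the top k; (c) tune (C, q) by inner-CV grid search on the
#' training subjects over the selected region kernels (plus any extra
#' modality blocks in multimodal mode); (d) train the MKL model; (e)
#' predict the held-out fold. The multiclass mode repeats (a)-(e) per
#' class pair inside each fold and combines pairwise predictions by
#' one-against-one voting. Labels are passed explicitly so permutation
#' tests can re-run the identical pipeline under relabelings.
#'
#' @param cache output of [prepare_cv_data()].
#' @param labels diagnosis per subject (defaults to the cohort's).
#' @param config pipeline configuration, see [default_config()].
#' @return An object of class `"cv_report"` with per-fold records
#'   (test ids and indices, truth, predictions, decision values,
#'   selected regions, chosen C and q, training ids for audit) and
#'   pooled aggregate metrics.
#' @export
run_cv_features <- function(cache, labels = cache$labels,
                            config = cache$config) {
  config <- merge_config(config)
  n <- length(labels)
  folds <- stratified_kfold(labels, config$k, seed = config$seed)
  mode <- config$mode
  pos_name <- config$positive_name
  truth <- if (mode == "multiclass") labels
           else ifelse(labels == config$idiopathic_class,
                       config$idiopathic_class, pos_name)
  pred <- character(n)
  decision <- rep(NA_real_, n)
  fold_records <- vector("list", config$k)
  for (f in sort(unique(folds))) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(unique(labels[tr])) < 2)
      stop("training partition of fold ", f, " contains a single class")
    fold_seed <- config$seed * 1000L + f
    if (mode %in% c("binary", "multimodal")) {
      y_tr <- ifelse(labels[tr] == config$idiopathic_class, -1, 1)
      if (length(unique(y_tr)) < 2)
        stop("training partition of fold ", f, " contains a single class")
      ffit <- fit_fold_binary(cache, tr, y_tr, config, fold_seed)
      g <- fold_decision(ffit, tr, te)
      pred[te] <- ifelse(g >= 0, pos_name, config$idiopathic_class)
      decision[te] <- g
      fold_records[[f]] <- list(fold = f, test_ids = cache$ids[te],
                                test_index = te, truth = truth[te],
                                pred = pred[te], decision = g,
                                regions = ffit$regions, C = ffit$C,
                                q = ffit$q, train_ids = cache$ids[tr])
    } else {
      classes <- sort(unique(labels))
      pair_list <- combn(classes, 2, simplify = FALSE)
      votes <- matrix(0L, length(te), length(classes),
                      dimnames = list(NULL, classes))
      marg <- matrix(0, length(te), length(classes),
                     dimnames = list(NULL, classes))
      pair_info <- list()
      for (p in pair_list) {
        trp <- tr[labels[tr] %in% p]
        y_trp <- ifelse(labels[trp] == p[2], 1, -1)
        ffit <- fit_fold_binary(cache, trp, y_trp, config, fold_seed)
        g <- fold_decision(ffit, trp, te)
        winner <- ifelse(g >= 0, p[2], p[1])
        for (i in seq_along(te)) {
          votes[i, winner[i]] <- votes[i, winner[i]] + 1L
          marg[i, winner[i]] <- marg[i, winner[i]] + abs(g[i])
        }
        pair_info[[paste(p, collapse = "|")]] <-
          list(regions = ffit$regions, C = ffit$C, q = ffit$q)
      }
      pred[te] <- vapply(seq_along(te), function(i) {
        top <- which(votes[i, ] == max(votes[i, ]))
        if (length(top) > 1) {
          best <- top[marg[i, top] == max(marg[i, top])]
          classes[min(best)]
        } else classes[top]
      }, character(1))
      fold_records[[f]] <- list(fold = f, test_ids = cache$ids[te],
                                test_index = te, truth = truth[te],
                                pred = pred[te], pairs = pair_info,
                                train_ids = cache$ids[tr])
    }
  }
  agg <- if (mode == "multiclass") metrics(truth, pred)
         else metrics(truth, pred, positive = pos_name)
  structure(list(folds = fold_records, fold_assignment = folds,
                 ids = cache$ids, truth = truth, pred = pred,
                 decision = decision, mode = mode,
                 accuracy = agg$accuracy,
                 sensitivity = agg$sensitivity,
                 specificity = agg$specificity,
                 per_class = agg$per_class,
                 config = config),
            class = "cv_report")
}

#' Run the full cross-validated MKL pipeline on a cohort
#'
#' Convenience wrapper: [prepare_cv_data()] then [run_cv_features()].
#'
#' @inheritParams prepare_cv_data
#' @return A `"cv_report"`, with the cache attached as attribute
#'   `"cache"` for reuse (e.g. permutation tests, ROC).
#' @export
run_cv_pipeline <- function(subjects, a, config = default_config()) {
  cache <- prepare_cv_data(subjects, a, config)
  rep <- run_cv_features(cache, cache$labels, cache$config)
  attr(rep, "cache") <- cache
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> mode=%s, k=%d, accuracy %.2f%%\n",
              x$mode, length(x$folds), 100 * x$accuracy))
  if (!is.null(x$sensitivity))
    cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%\n",
                100 * x$sensitivity, 100 * x$specificity))
  if (!is.null(x$per_class)) {
    for (cl in names(x$per_class))
      cat(sprintf("  %s accuracy %.2f%%\n", cl, 100 * x$per_class[cl]))
  }
  invisible(x)
}

#' Serialize a CV report to JSON
#'
#' @param report a `"cv_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_cv_report <- function(report, path) {
  obj <- unclass(report)
  attr(obj, "cache") <- NULL
  obj$config <- unclass(obj$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
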