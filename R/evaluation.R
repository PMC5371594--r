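#' Stratified k-fold assignment
#'
#' Shuffles subjects within each class (seeded) and deals them to folds
#' round-robin, continuing the fold pointer across classes so that both
#' overall fold sizes and per-class counts per fold differ by at most 1.
#'
#' @param labels class label per subject.
#' @param k number of folds.
#' @param seed optional seed for the shuffle.
#' @return Integer fold assignment in `1..k`, one entry per subject.
#' @export
stratified_kfold <- function(labels, k = 10, seed = NULL) {
  n <- length(labels)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of subjects")
  if (!is.null(seed)) set.seed(seed)
  small <- table(labels) < k
  if (any(small))
    warning("class(es) with fewer than k members; stratification relaxed: ",
            paste(names(which(small)), collapse = ", "))
  folds <- integer(n)
  ptr <- 0L
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
    ptr <- ptr + length(idx)
  }
  folds
}

#' Enumerate simplex-lattice kernel weights
#'
#' All weight vectors with entries on the `step` lattice, each at least
#' `step`, summing to 1 — the grid-search candidates for the kernel
#' weights. With one kernel the single vector `(1.0)` is returned.
#'
#' @param n_k number of kernels.
#' @param step lattice step; must divide 1.
#' @return List of numeric weight vectors in lexicographic order.
#' @export
enumerate_simplex_grid <- function(n_k, step = 0.1) {
  if (n_k < 1) stop("n_k must be at least 1")
  units <- round(1 / step)
  if (abs(units * step - 1) > 1e-9) stop("`step` must divide 1")
  if (n_k == 1) return(list(1.0))
  if (n_k > units)
    stop("infeasible grid: n_k * step exceeds 1")
  comps <- function(total, parts) {
    if (parts == 1) return(list(total))
    out <- list()
    for (f in seq(1, total - parts + 1))
      out <- c(out, lapply(comps(total - f, parts - 1),
                           function(rest) c(f, rest)))
    out
  }
  lapply(comps(units, n_k), function(cc) cc * step)
}

#' Classification metrics
#'
#' With a `positive` class: accuracy, sensitivity (true-positive rate of
#' the positive class) and specificity (true-negative rate). Without:
#' overall accuracy plus per-class accuracies (recall per class).
#' All rates are proportions in [0, 1].
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive optional name of the positive class.
#' @return A list with `accuracy` and either
#'   `sensitivity`/`specificity` or `per_class`.
#' @export
metrics <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty input")
  acc <- mean(y_true == y_pred)
  if (!is.null(positive)) {
    if (!any(y_true == positive))
      stop("positive class absent from y_true: ", positive)
    if (all(y_true == positive))
      stop("negative class absent from y_true")
    list(accuracy = acc,
         sensitivity = mean(y_pred[y_true == positive] == positive),
         specificity = mean(y_pred[y_true != positive] != positive))
  } else {
    classes <- sort(unique(y_true))
    per <- vapply(classes, function(cl)
      mean(y_pred[y_true == cl] == cl), numeric(1))
    names(per) <- classes
    list(accuracy = acc, per_class = per)
  }
}

#' Grid search over (C, q) by inner cross-validation
#'
#' Evaluates every combination of the C grid and the simplex lattice of
#' kernel weights by stratified inner k-fold cross-validation on the
#' training kernels, and returns the combination with the highest pooled
#' accuracy. Ties prefer the smaller C, then the lexicographically
#' smallest q. With a single candidate the inner loop is skipped.
#'
#' @param kernels list of square train kernels (one per block).
#' @param y training labels coded -1/+1.
#' @param C_grid candidate box constraints (ascending recommended).
#' @param q_step simplex lattice step for the weights.
#' @param inner_k number of inner folds.
#' @param seed seed for the inner fold shuffle.
#' @return List with `C`, `q`, `accuracy` (inner-CV estimate, `NA` for
#'   a single candidate) and `n_candidates`.
#' @export
grid_search <- function(kernels, y, C_grid = 2^(-3:5), q_step = 0.1,
                        inner_k = 5, seed = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("degenerate training set: one class")
  qs <- enumerate_simplex_grid(length(kernels), q_step)
  C_grid <- sort(C_grid)
  if (any(C_grid <= 0)) stop("C values must be positive")
  if (length(qs) == 1 && length(C_grid) == 1)
    return(list(C = C_grid[1], q = qs[[1]], accuracy = NA_real_,
                n_candidates = 1L))
  n <- length(y)
  folds <- stratified_kfold(y, min(inner_k, min(table(y))), seed = seed)
  correct <- matrix(0L, length(C_grid), length(qs))
  for (qi in seq_along(qs)) {
    Kq <- combine_kernels(kernels, qs[[qi]])
    for (f in sort(unique(folds))) {
      te <- folds == f
      tr <- !te
      if (length(unique(y[tr])) < 2) next
      Ktr <- Kq[tr, tr, drop = FALSE]
      Kte <- Kq[te, tr, drop = FALSE]
      for (ci in seq_along(C_grid)) {
        fit <- train_svm(Ktr, y[tr], C_grid[ci])
        pred <- ifelse(decision_values(fit, Kte) >= 0, 1, -1)
        correct[ci, qi] <- correct[ci, qi] + sum(pred == y[te])
      }
    }
  }
  best <- which(correct == max(correct), arr.ind = TRUE)
  # ties: smallest C first, then lexicographically smallest q
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(C = C_grid[best[1]], q = qs[[best[2]]],
       accuracy = max(correct) / n,
       n_candidates = length(C_grid) * length(qs))
}

#' Permutation test of an accuracy statistic
#'
#' Re-runs the full analysis closure under random relabelings of the
#' cohort and reports the fraction of permuted runs whose accuracy is
#' greater than or equal to the observed one. The optional
#' `(b + 1) / (m + 1)` correction is available but off by default.
#'
#' @param stat_fn function mapping a label vector to an accuracy.
#' @param labels the true labels.
#' @param n_perm number of permutations.
#' @param seed optional seed for the permutations.
#' @param plus_one use the `(b + 1) / (m + 1)` estimator.
#' @return An object of class `"permutation_result"`: `observed`,
#'   `null` (length `n_perm`), `p_value`, `n_perm`.
#' @export
permutation_test <- function(stat_fn, labels, n_perm = 1000, seed = NULL,
                             plus_one = FALSE) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  observed <- stat_fn(labels)
  if (!is.null(seed)) set.seed(seed)
  # draw every relabeling before invoking the statistic: the pipeline
  # closure seeds its own fold shuffles, which would otherwise reset the
  # stream between permutations
  perms <- lapply(seq_len(n_perm), function(i) sample(length(labels)))
  null <- vapply(perms, function(p) stat_fn(labels[p]), numeric(1))
  b <- sum(null >= observed)
  p <- if (plus_one) (b + 1) / (n_perm + 1) else b / n_perm
  structure(list(observed = observed, null = null, p_value = p,
                 n_perm = n_perm, plus_one = plus_one),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score thresholds and reports (FPR, TPR) pairs and
#' the trapezoid AUC, which equals the Mann-Whitney statistic with ties
#' counted 1/2. Higher scores are treated as more positive.
#'
#' @param scores numeric decision values.
#' @param labels class labels.
#' @param positive name of the positive class.
#' @return An object of class `"roc_result"`: `thresholds`, `fpr`,
#'   `tpr` (monotone from (0,0) to (1,1)), `auc`.
#' @export
roc_curve <- function(scores, labels, positive) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  resp <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  r <- pROC::roc(resp, scores, direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  structure(list(thresholds = r$thresholds[ord],
                 fpr = (1 - r$specificities)[ord],
                 tpr = r$sensitivities[ord],
                 auc = as.numeric(pROC::auc(r))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' 26-connected components of a logical 3-D mask
#'
#' @param mask logical 3-D array.
#' @return Integer array of cluster ids (0 = background), labelled in
#'   decreasing cluster size.
#' @export
label_clusters <- function(mask) {
  d <- dim(mask)
  cl <- array(0L, d)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  nid <- 0L
  for (seed in which(mask & cl == 0L)) {
    if (cl[seed] != 0L) next
    nid <- nid + 1L
    cl[seed] <- nid
    queue <- seed
    while (length(queue)) {
      co <- arrayInd(queue, d)
      queue <- integer(0)
      for (o in seq_len(nrow(offsets))) {
        nb <- co + matrix(offsets[o, ], nrow(co), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
               (nb[ok, 3] - 1L) * d[1] * d[2]
        new <- lin[mask[lin] & cl[lin] == 0L]
        if (length(new)) {
          new <- unique(new)
          cl[new] <- nid
          queue <- c(queue, new)
        }
      }
    }
  }
  if (nid > 1) {  # relabel by decreasing size
    sizes <- tabulate(cl[cl > 0L], nid)
    remap <- integer(nid)
    remap[order(-sizes)] <- seq_len(nid)
    cl[cl > 0L] <- remap[cl[cl > 0L]]
  }
  cl
}

#' Voxelwise two-sample t-map with cluster table
#'
#' Pooled-variance two-sample t-statistic per voxel with
#' `df = n1 + n2 - 2`, z-scores via the one-sided tail mapping
#' `P(Z > z) = P(T > t)`, and 26-connected suprathreshold clusters at an
#' uncorrected threshold. Voxels with zero pooled variance get `t = 0`
#' and are flagged. Inputs are expected pre-smoothed.
#'
#' @param group_a,group_b lists of [volume()]s on a shared grid (at
#'   least 2 each).
#' @param p_thresh uncorrected p threshold defining suprathreshold
#'   voxels.
#' @param direction `"greater"` (A > B), `"less"` or `"two.sided"`.
#' @return An object of class `"t_map"`: `t` and `z` volumes, `df`,
#'   `clusters` (data frame: cluster, n_voxels, volume_mm3, peak_t,
#'   peak_z), `cluster_map`, `undefined` flag array, `t_crit`.
#' @export
voxelwise_ttest <- function(group_a, group_b, p_thresh = 0.001,
                            direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 volumes per group")
  d <- dim(group_a[[1]]$data)
  for (v in c(group_a, group_b))
    if (!all(dim(v$data) == d)) stop("mismatched grids")
  sum_sq <- function(vols, m) Reduce(`+`, lapply(vols, function(v)
    (v$data - m)^2))
  m1 <- Reduce(`+`, lapply(group_a, `[[`, "data")) / n1
  m2 <- Reduce(`+`, lapply(group_b, `[[`, "data")) / n2
  df <- n1 + n2 - 2
  sp2 <- (sum_sq(group_a, m1) + sum_sq(group_b, m2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  undefined <- se == 0
  tv <- (m1 - m2) / ifelse(undefined, 1, se)
  tv[undefined] <- 0
  zv <- qnorm(pt(tv, df, lower.tail = FALSE, log.p = TRUE),
              lower.tail = FALSE, log.p = TRUE)
  geom <- group_a[[1]]
  t_crit <- if (direction == "two.sided") qt(1 - p_thresh / 2, df)
            else qt(1 - p_thresh, df)
  supra <- switch(direction,
                  greater = tv > t_crit,
                  less = tv < -t_crit,
                  two.sided = abs(tv) > t_crit)
  cl <- label_clusters(supra)
  ids <- if (max(cl) > 0) seq_len(max(cl)) else integer(0)
  clusters <- do.call(rbind, lapply(ids, function(i) {
    vox <- which(cl == i)
    peak <- vox[which.max(abs(tv[vox]))]
    data.frame(cluster = i, n_voxels = length(vox),
               volume_mm3 = length(vox) * prod(geom$voxel_size),
               peak_t = tv[peak], peak_z = zv[peak])
  }))
  if (is.null(clusters))
    clusters <- data.frame(cluster = integer(0), n_voxels = integer(0),
                           volume_mm3 = numeric(0), peak_t = numeric(0),
                           peak_z = numeric(0))
  structure(list(t = volume(tv, geom$voxel_size, geom$affine),
                 z = volume(zv, geom$voxel_size, geom$affine),
                 df = df, clusters = clusters, cluster_map = cl,
                 undefined = undefined, t_crit = t_crit,
                 p_thresh = p_thresh, direction = direction),
            class = "t_map")
}

#' @export
print.t_map <- function(x, ...) {
  cat(sprintf("<t_map> df = %d, %d cluster(s) at p < %g (%s)\n",
              x$df, nrow(x$clusters), x$p_thresh, x$direction))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
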