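#' Train a multiple kernel learning SVM over feature blocks
#'
#' Builds one linear kernel per feature block, combines them with the
#' simplex weights `q`, and trains a soft-margin SVM on the combined
#' kernel. With a one-hot `q` this is exactly the single-kernel SVM on
#' that block.
#'
#' @param blocks named list of training feature matrices (one per block,
#'   shared row/subject order).
#' @param y labels coded -1/+1.
#' @param C positive box constraint.
#' @param q kernel weights (defaults to uniform), see [mkl_weights()].
#' @param label_map optional `neg`/`pos` class names (see
#'   [train_svm()]).
#' @param ... passed to [train_svm()].
#' @return An object of class `"mkl_fit"` holding the inner `"svm_fit"`,
#'   the weights `q`, the block names and the training blocks needed to
#'   evaluate kernels on new samples.
#' @export
train_mkl <- function(blocks, y, C, q = NULL, label_map = NULL, ...) {
  if (length(blocks) == 0) stop("no feature blocks given")
  n <- nrow(blocks[[1]])
  for (b in blocks) if (nrow(b) != n) stop("blocks disagree on subjects")
  if (is.null(q)) q <- rep(1 / length(blocks), length(blocks))
  if (length(q) != length(blocks)) stop("need one weight per block")
  mkl_weights(q)
  kernels <- lapply(blocks, tcrossprod)
  K <- combine_kernels(kernels, q)
  svm <- train_svm(K, y, C, label_map = label_map, ...)
  structure(list(svm = svm, q = q, block_names = names(blocks),
                 blocks = blocks, label_map = label_map),
            class = "mkl_fit")
}

#' @export
print.mkl_fit <- function(x, ...) {
  cat(sprintf("<mkl_fit> %d blocks, C=%g\n", length(x$blocks), x$svm$C))
  for (m in seq_along(x$blocks))
    cat(sprintf("  q=%.2f  %s\n", x$q[m],
                x$block_names[m] %||% paste0("block ", m)))
  invisible(x)
}

#' Combined test kernel of an MKL model
#'
#' @param model an `"mkl_fit"`.
#' @param newblocks list of test feature matrices matching the training
#'   blocks in order and feature dimension.
#' @return Test-by-train combined kernel matrix.
#' @export
mkl_test_kernel <- function(model, newblocks) {
  stopifnot(inherits(model, "mkl_fit"))
  if (length(newblocks) != length(model$blocks))
    stop("need one test block per training block")
  kernels <- Map(function(Xn, Xt) linear_kernel(as.matrix(Xn), Xt),
                 newblocks, model$blocks)
  combine_kernels(kernels, model$q)
}

#' Predict from a trained MKL model
#'
#' @param object an `"mkl_fit"`.
#' @param newblocks list of test feature matrices (one per training
#'   block).
#' @param type `"class"` or `"decision"`.
#' @param ... unused.
#' @return Class labels or decision values.
#' @export
predict.mkl_fit <- function(object, newblocks,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  predict(object$svm, mkl_test_kernel(object, newblocks), type = type)
}

#' Train a one-against-one multiclass ensemble
#'
#' One binary MKL model per unordered class pair, each trained only on
#' its pair's samples. Within a pair the alphabetically later class is
#' coded +1.
#'
#' @param fs a `"feature_set"` (see [build_feature_sets()]).
#' @param C box constraint shared by the pairwise models.
#' @param q kernel weights shared by the pairwise models (default
#'   uniform).
#' @param classes classes to include (default: all present).
#' @return An object of class `"ovo_ensemble"`.
#' @export
train_ovo <- function(fs, C = 1, q = NULL,
                      classes = sort(unique(fs$labels))) {
  stopifnot(inherits(fs, "feature_set"))
  classes <- sort(classes)
  if (length(classes) < 2) stop("need at least two classes")
  for (cl in classes)
    if (sum(fs$labels == cl) < 2)
      stop("class with fewer than 2 samples: ", cl)
  pairs <- combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    rows <- fs$labels %in% p
    enc <- encode_labels(fs$labels[rows], positive = p[2],
                         pos_name = p[2], neg_name = p[1])
    blocks <- lapply(fs$blocks, function(b) b[rows, , drop = FALSE])
    train_mkl(blocks, enc$y, C, q, label_map = enc$label_map)
  })
  names(models) <- vapply(pairs, paste, character(1), collapse = "|")
  structure(list(models = models, classes = classes),
            class = "ovo_ensemble")
}

#' Predict by one-against-one majority vote
#'
#' Each pairwise model votes for one class; the class with most votes
#' wins. Ties are broken by the largest sum of winning decision-value
#' magnitudes, then alphabetically.
#'
#' @param ensemble an `"ovo_ensemble"`.
#' @param newblocks list of test feature matrices matching the feature
#'   set used for training (full blocks; pairwise subsetting of columns
#'   is not needed since blocks are shared).
#' @return Character vector of predicted classes.
#' @export
predict_ovo <- function(ensemble, newblocks) {
  stopifnot(inherits(ensemble, "ovo_ensemble"))
  n <- nrow(as.matrix(newblocks[[1]]))
  classes <- ensemble$classes
  votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  margin <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (m in ensemble$models) {
    g <- predict(m, newblocks, type = "decision")
    winner <- ifelse(g >= 0, m$label_map[["pos"]], m$label_map[["neg"]])
    for (i in seq_len(n)) {
      votes[i, winner[i]] <- votes[i, winner[i]] + 1L
      margin[i, winner[i]] <- margin[i, winner[i]] + abs(g[i])
    }
  }
  vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      best <- top[margin[i, top] == max(margin[i, top])]
      classes[min(best)]
    } else classes[top]
  }, character(1))
}

#' Serialize an MKL model to JSON
#'
#' Stores dual coefficients, bias, C, kernel weights, block names and
#' the training blocks (needed to evaluate kernels on new samples).
#'
#' @param model an `"mkl_fit"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_mkl_model <- function(model, path) {
  stopifnot(inherits(model, "mkl_fit"))
  obj <- list(alpha = model$svm$alpha, coef = model$svm$coef,
              y = model$svm$y, bias = model$svm$bias, C = model$svm$C,
              q = model$q, block_names = model$block_names,
              label_map = model$label_map,
              blocks = lapply(model$blocks, function(b)
                list(dim = dim(b), data = as.numeric(b))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Load an MKL model saved by [save_mkl_model()]
#'
#' @param path JSON path.
#' @return The reconstituted `"mkl_fit"`.
#' @export
load_mkl_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- lapply(obj$blocks, function(b)
    matrix(b$data, b$dim[1], b$dim[2]))
  lm <- if (is.null(obj$label_map)) NULL else as.list(obj$label_map)
  svm <- structure(list(alpha = obj$alpha, coef = obj$coef,
                        bias = obj$bias, C = obj$C,
                        support_index = which(obj$alpha > 1e-8 * obj$C),
                        objective = NA_real_, iterations = NA_integer_,
                        converged = TRUE, y = obj$y, label_map = lm),
                   class = "svm_fit")
  structure(list(svm = svm, q = obj$q, block_names = obj$block_names,
                 blocks = blocks, label_map = lm),
            class = "mkl_fit")
}
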