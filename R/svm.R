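#' Linear kernel matrix
#'
#' Entry (i, j) is the dot product of row i of `X` and row j of `Y`.
#'
#' @param X,Y sample-by-feature matrices with matching feature dimension
#'   (`Y` defaults to `X`).
#' @return The `nrow(X) x nrow(Y)` kernel matrix.
#' @export
linear_kernel <- function(X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("feature dimensions do not match: ", ncol(X), " vs ", ncol(Y))
  X %*% t(Y)
}

#' Validate multiple-kernel weights
#'
#' Kernel weights must be nonnegative and sum to 1.
#'
#' @param q numeric weight vector.
#' @return `q`, invisibly, after validation.
#' @export
mkl_weights <- function(q) {
  if (!is.numeric(q) || length(q) < 1) stop("`q` must be numeric")
  if (any(q < 0)) stop("kernel weights must be nonnegative")
  if (abs(sum(q) - 1) > 1e-8) stop("kernel weights must sum to 1")
  invisible(q)
}

#' Linear combination of kernel matrices
#'
#' Computes the weighted sum `sum_m q_m K_m` over per-block kernels.
#'
#' @param kernels list of kernel matrices of identical shape.
#' @param q weight vector satisfying [mkl_weights()].
#' @return The combined kernel matrix.
#' @export
combine_kernels <- function(kernels, q) {
  if (length(kernels) == 0) stop("no kernels given")
  if (length(kernels) != length(q))
    stop("need one weight per kernel")
  mkl_weights(q)
  d <- dim(kernels[[1]])
  for (K in kernels)
    if (!all(dim(K) == d)) stop("kernel shapes do not match")
  out <- q[1] * kernels[[1]]
  for (m in seq_along(kernels)[-1]) out <- out + q[m] * kernels[[m]]
  out
}

check_kernel_square <- function(K, y) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("kernel must be a square matrix")
  if (nrow(K) != length(y))
    stop("kernel size does not match the labels")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-8 * max(1, max(abs(K))))
    stop("kernel is not symmetric (max asymmetry ", signif(asym, 3), ")")
  (K + t(K)) / 2
}

#' Train a soft-margin SVM in the dual over a precomputed kernel
#'
#' Solves the dual quadratic program
#' `max sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij` subject to
#' `0 <= alpha_i <= C` and `sum alpha_i y_i = 0` by sequential minimal
#' optimization with maximal-violating-pair selection, to a KKT
#' violation below `eps`. The bias is the mean of
#' `y_i - sum_j alpha_j y_j K_ji` over free support vectors
#' (`0 < alpha_i < C`), or the midpoint of the feasible interval when no
#' free vector exists.
#'
#' @param K square symmetric kernel over the training samples.
#' @param y labels, coded -1/+1; both classes must be present.
#' @param C positive box constraint (error/simplicity trade-off).
#' @param eps KKT violation tolerance of the solver.
#' @param max_iter iteration cap for the solver.
#' @param label_map optional named list/vector with entries `neg` and
#'   `pos` giving class names for the -1/+1 codes.
#' @param check_psd verify positive semidefiniteness first and
#'   ridge-regularize the diagonal (with a warning) if violated; off by
#'   default because linear kernels are PSD by construction.
#' @return An object of class `"svm_fit"`: `alpha`, `coef`
#'   (`alpha * y`), `bias`, `C`, `support_index`, `objective` (dual
#'   value), `iterations`, `converged`, `y`, `label_map`.
#' @export
train_svm <- function(K, y, C, eps = 1e-8, max_iter = 200000L,
                      label_map = NULL, check_psd = FALSE) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be coded -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (!is.numeric(C) || length(C) != 1 || C <= 0)
    stop("`C` must be a single positive number")
  K <- check_kernel_square(K, y)
  if (check_psd) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    tol <- 1e-8 * max(1, max(abs(diag(K))))
    if (min(ev) < -tol) {
      warning("kernel is not positive semidefinite; regularizing diagonal")
      K <- K + diag(-min(ev) + tol, nrow(K))
    }
  }
  sol <- .smo_solve(K, y, C, eps, as.integer(max_iter))
  alpha <- sol$alpha
  coef <- alpha * y
  g0 <- drop(K %*% coef)
  tol_a <- 1e-8 * C
  free <- alpha > tol_a & alpha < C - tol_a
  if (any(free)) {
    bias <- mean(y[free] - g0[free])
  } else {
    # feasible interval from the bound-constrained KKT inequalities
    lo <- c((y - g0)[y > 0 & alpha <= tol_a],
            (y - g0)[y < 0 & alpha >= C - tol_a])
    up <- c((y - g0)[y < 0 & alpha <= tol_a],
            (y - g0)[y > 0 & alpha >= C - tol_a])
    lo <- if (length(lo)) max(lo) else -Inf
    up <- if (length(up)) min(up) else Inf
    bias <- if (is.finite(lo) && is.finite(up)) (lo + up) / 2
            else if (is.finite(lo)) lo else if (is.finite(up)) up else 0
  }
  structure(list(alpha = alpha, coef = coef, bias = bias, C = C,
                 support_index = which(alpha > tol_a),
                 objective = sum(alpha) - 0.5 * sum(coef * g0),
                 iterations = sol$iterations, converged = sol$converged,
                 y = y, label_map = label_map),
            class = "svm_fit")
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("<svm_fit> n=%d, C=%g, %d support vectors, dual objective %.6g\n",
              length(x$alpha), x$C, length(x$support_index), x$objective))
  invisible(x)
}

#' Decision values of a trained SVM
#'
#' Computes `g(x) = sum_j alpha_j y_j K(x, x_j) + bias` for each test
#' sample.
#'
#' @param model an `"svm_fit"`.
#' @param K_test test-by-train kernel matrix (or a vector for a single
#'   sample).
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, K_test) {
  stopifnot(inherits(model, "svm_fit"))
  if (is.vector(K_test)) K_test <- matrix(K_test, nrow = 1)
  if (ncol(K_test) != length(model$coef))
    stop("K_test columns must match the training samples")
  drop(K_test %*% model$coef + model$bias)
}

#' Predict classes from a trained SVM
#'
#' Labels follow the side of the hyperplane; a decision value of exactly
#' 0 is assigned to the +1 class.
#'
#' @param object an `"svm_fit"`.
#' @param K_test test-by-train kernel matrix.
#' @param type `"class"` for labels, `"decision"` for raw values.
#' @param ... unused.
#' @return Class labels (mapped through `label_map` when present) or
#'   decision values.
#' @export
predict.svm_fit <- function(object, K_test, type = c("class", "decision"),
                            ...) {
  type <- match.arg(type)
  g <- decision_values(object, K_test)
  if (type == "decision") return(g)
  s <- ifelse(g >= 0, 1, -1)
  if (!is.null(object$label_map))
    ifelse(s > 0, object$label_map[["pos"]], object$label_map[["neg"]])
  else s
}

#' Primal weight vector of a linear-kernel SVM
#'
#' For a model trained on the linear kernel of `X_train`,
#' `w = sum_i alpha_i y_i x_i`; the primal decision `w . x + bias`
#' agrees with the kernel form.
#'
#' @param model an `"svm_fit"` trained on `linear_kernel(X_train)`.
#' @param X_train the training feature matrix.
#' @return Numeric weight vector of length `ncol(X_train)`.
#' @export
weight_vector <- function(model, X_train) {
  stopifnot(inherits(model, "svm_fit"))
  X_train <- as.matrix(X_train)
  if (nrow(X_train) != length(model$coef))
    stop("X_train rows must match the training samples")
  drop(crossprod(X_train, model$coef))
}

#' Encode class labels as -1/+1
#'
#' @param labels character vector of class labels.
#' @param positive labels belonging to the +1 class (one or more class
#'   names, e.g. both atypical syndromes).
#' @param pos_name,neg_name names reported for the two codes.
#' @return List with `y` (numeric -1/+1) and `label_map`.
#' @export
encode_labels <- function(labels, positive,
                          pos_name = paste(positive, collapse = "+"),
                          neg_name = NULL) {
  pos <- labels %in% positive
  if (!any(pos) || all(pos))
    stop("both classes must be present after encoding")
  if (is.null(neg_name))
    neg_name <- paste(sort(unique(labels[!pos])), collapse = "+")
  list(y = ifelse(pos, 1, -1), label_map = list(neg = neg_name,
                                                pos = pos_name))
}
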