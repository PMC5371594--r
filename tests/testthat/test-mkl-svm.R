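test_that("linear kernel is a dot-product matrix, symmetric PSD", {
  X <- rbind(c(1, 0), c(0, 1))
  expect_equal(linear_kernel(X), diag(2))
  expect_equal(linear_kernel(matrix(c(2, 3), 1), matrix(c(1, 1), 1)),
               matrix(5))
  set.seed(4)
  X <- matrix(rnorm(40), 10, 4)
  K <- linear_kernel(X)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_error(linear_kernel(X, matrix(0, 2, 3)), "dimensions")
})

test_that("kernel combination is the weighted sum with simplex weights", {
  K <- matrix(c(2, 1, 1, 3), 2)
  expect_equal(combine_kernels(list(K), 1), K)
  expect_equal(combine_kernels(list(K, K), c(0.5, 0.5)), K)
  expect_equal(combine_kernels(list(matrix(1), matrix(2)), c(0.3, 0.7)),
               matrix(1.7))
  expect_error(combine_kernels(list(K, matrix(0, 3, 3)), c(0.5, 0.5)),
               "shapes")
  expect_error(combine_kernels(list(K, K), c(0.4, 0.4)), "sum to 1")
  expect_error(combine_kernels(list(K, K), c(-0.2, 1.2)), "nonnegative")

  # PSD is preserved under nonnegative combination
  set.seed(9)
  Ks <- lapply(1:3, function(i) tcrossprod(matrix(rnorm(24), 8)))
  Kc <- combine_kernels(Ks, c(0.2, 0.3, 0.5))
  expect_gte(min(eigen(Kc, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("the two-point margin problem has its analytic solution", {
  X <- matrix(c(-1, 1), ncol = 1)
  fit <- train_svm(linear_kernel(X), c(-1, 1), C = 100)
  expect_equal(fit$alpha, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(fit$bias, 0, tolerance = 1e-8)
  expect_equal(weight_vector(fit, X), 1, tolerance = 1e-8)
  expect_equal(decision_values(fit, linear_kernel(matrix(2), X)), 2,
               tolerance = 1e-8)
  expect_equal(decision_values(fit, linear_kernel(matrix(0), X)), 0,
               tolerance = 1e-8)
})

test_that("solver satisfies the KKT conditions on random problems", {
  for (s in 1:10) {
    prob <- rand_svm_problem(s)
    fit <- train_svm(linear_kernel(prob$X), prob$y, prob$C)
    expect_true(fit$converged)
    v <- kkt_violations(fit, linear_kernel(prob$X), tol = 1e-4)
    expect_equal(sum(v), 0)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= prob$C + 1e-12))
    expect_lt(abs(sum(fit$coef)), 1e-8)   # sum alpha_i y_i = 0
  }
})

test_that("duplicated separable data keep the same decision boundary", {
  set.seed(12)
  X <- rbind(matrix(rnorm(10, -2), 5, 2), matrix(rnorm(10, 2), 5, 2))
  y <- rep(c(-1, 1), each = 5)
  fit1 <- train_svm(linear_kernel(X), y, C = 10)
  X2 <- rbind(X, X); y2 <- c(y, y)
  fit2 <- train_svm(linear_kernel(X2), y2, C = 10)
  Xt <- matrix(rnorm(20), 10, 2)
  expect_equal(decision_values(fit2, linear_kernel(Xt, X2)),
               decision_values(fit1, linear_kernel(Xt, X)),
               tolerance = 1e-5)
})

test_that("training rejects malformed inputs", {
  K <- linear_kernel(matrix(1:4, 2))
  expect_error(train_svm(K, c(1, 1), 1), "both classes")
  expect_error(train_svm(K, c(-1, 1), -1), "positive")
  expect_error(train_svm(matrix(c(1, 5, 0, 1), 2), c(-1, 1), 1),
               "symmetric")
  expect_error(train_svm(K, c(0, 1), 1), "-1/\\+1")
})

test_that("predictions follow the hyperplane side with sign(0) -> +1", {
  X <- matrix(c(-1, 1), ncol = 1)
  fit <- train_svm(linear_kernel(X), c(-1, 1), C = 100,
                   label_map = list(neg = "PD", pos = "atypical"))
  K_test <- linear_kernel(matrix(c(-2, 3, 0), ncol = 1), X)
  expect_equal(predict(fit, K_test), c("PD", "atypical", "atypical"))
  # invariance to positive rescaling of the decision values
  expect_equal(predict(fit, K_test * 10),
               predict(fit, K_test * 0.1))
})

test_that("primal and kernel decision values agree for linear models", {
  set.seed(31)
  X <- matrix(rnorm(60), 15, 4)
  y <- rep(c(-1, 1), length.out = 15)
  X[y > 0, 2] <- X[y > 0, 2] + 1.5
  fit <- train_svm(linear_kernel(X), y, C = 2)
  w <- weight_vector(fit, X)
  Xt <- matrix(rnorm(80), 20, 4)
  expect_equal(drop(Xt %*% w) + fit$bias,
               decision_values(fit, linear_kernel(Xt, X)),
               tolerance = 1e-8)

  # a constant feature column with balanced labels gets ~zero weight
  Xc <- cbind(X, 1)
  fitc <- train_svm(linear_kernel(Xc), y, C = 2)
  expect_lt(abs(weight_vector(fitc, Xc)[5]), 1e-6)
})

test_that("one-hot kernel weights reproduce the single-kernel SVM exactly", {
  set.seed(17)
  blocks <- list(A = matrix(rnorm(30), 10), B = matrix(rnorm(50), 10))
  y <- rep(c(-1, 1), each = 5)
  blocks$A[y > 0, ] <- blocks$A[y > 0, ] + 1
  single <- train_svm(tcrossprod(blocks$A), y, C = 2)
  onehot <- train_mkl(blocks, y, C = 2, q = c(1, 0))
  expect_identical(onehot$svm$alpha, single$alpha)
  expect_identical(onehot$svm$bias, single$bias)
  newb <- list(matrix(rnorm(12), 4), matrix(rnorm(20), 4))
  expect_equal(predict(onehot, newb, type = "decision"),
               decision_values(single, linear_kernel(newb[[1]], blocks$A)))
})

test_that("one-against-one ensembles train per pair and vote", {
  set.seed(23)
  n <- 8
  mk_subject <- function(i, g, shift) {
    list(id = sprintf("%s%02d", g, i), diagnosis = g,
         volumes = list(dmfp = volume(array(rnorm(216, shift), c(6, 6, 6)))))
  }
  subjects <- c(lapply(1:n, mk_subject, g = "PD", shift = -2),
                lapply(1:n, mk_subject, g = "MSA", shift = 0),
                lapply(1:n, mk_subject, g = "PSP", shift = 2))
  fs <- build_feature_sets(subjects, tiny_atlas(),
                           c("region-A", "putamen"), "dmfp")
  ens <- train_ovo(fs, C = 1)
  expect_length(ens$models, 3)
  expect_named(ens$models, c("MSA|PD", "MSA|PSP", "PD|PSP"))
  # pairwise models never see the third class
  expect_equal(nrow(ens$models[["MSA|PD"]]$blocks[[1]]), 2 * n)
  # perfectly separated classes: 100% training-set vote agreement
  pred <- predict_ovo(ens, fs$blocks)
  expect_equal(pred, fs$labels)

  two <- build_feature_sets(subjects[1:16], tiny_atlas(),
                            c("region-A", "putamen"), "dmfp")
  ens2 <- train_ovo(two, C = 1)
  expect_length(ens2$models, 1)
  one <- build_feature_sets(subjects[c(1:8, 9)], tiny_atlas(),
                            c("region-A", "putamen"), "dmfp")
  expect_error(train_ovo(one, C = 1), "fewer than 2")
})

test_that("three-way vote ties fall to the largest decision magnitude", {
  # three 1-D pairwise models with midpoints -1, +1, 0: a sample at
  # x = 0.5 collects one vote per class with margins 1.5 / 0.5 / 0.5
  mk_pair <- function(x_neg, x_pos, neg, pos) {
    X <- matrix(c(x_neg, x_pos), ncol = 1)
    train_mkl(list(X), c(-1, 1), C = 100,
              label_map = list(neg = neg, pos = pos))
  }
  ens <- structure(list(models = list(mk_pair(-2, 0, "A", "B"),
                                      mk_pair(0, 2, "A", "C"),
                                      mk_pair(-4, 4, "B", "C")),
                        classes = c("A", "B", "C")),
                   class = "ovo_ensemble")
  expect_equal(predict_ovo(ens, list(matrix(0.5))), "B")
  # majority vote without tie: (B, C, C) -> C
  expect_equal(predict_ovo(ens, list(matrix(1.5))), "C")
})

test_that("MKL models survive JSON serialization", {
  set.seed(41)
  blocks <- list(A = matrix(rnorm(30), 10), B = matrix(rnorm(20), 10))
  y <- rep(c(-1, 1), 5)
  model <- train_mkl(blocks, y, C = 1, q = c(0.3, 0.7),
                     label_map = list(neg = "PD", pos = "atypical"))
  path <- withr::local_tempfile(fileext = ".json")
  save_mkl_model(model, path)
  back <- load_mkl_model(path)
  newb <- list(matrix(rnorm(6), 2), matrix(rnorm(4), 2))
  expect_equal(predict(back, newb, type = "decision"),
               predict(model, newb, type = "decision"), tolerance = 1e-12)
  expect_equal(predict(back, newb), predict(model, newb))
})
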