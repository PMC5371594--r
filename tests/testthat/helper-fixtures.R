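# Shared fixtures: all data are generated in code at test time.

rand_volume <- function(d = c(8, 8, 8), seed = 1, voxel_size = c(2, 2, 2)) {
  set.seed(seed)
  volume(array(runif(prod(d)), d), voxel_size)
}

# tiny two-region atlas on a 6x6x6 grid for parcellation arithmetic
tiny_atlas <- function() {
  lab <- array(0L, c(6, 6, 6))
  lab[2:3, 2:3, 2:3] <- 1L   # region-A (8 voxels)
  lab[5, 5, 5] <- 2L         # region-B (1 voxel)
  lab[2:3, 5, 2] <- 3L       # putamen-L (2 voxels)
  lab[5, 2, 5] <- 4L         # putamen-R (1 voxel)
  atlas(lab, c("1" = "region-A", "2" = "region-B",
               "3" = "putamen-L", "4" = "putamen-R"),
        voxel_size = c(2, 2, 2))
}

# independent QP oracle for the SVM dual (interior point, kernlab),
# with graded precision fallback for ill-conditioned draws
qp_dual_oracle <- function(K, y, C) {
  Q <- (y %o% y) * K
  n <- length(y)
  for (sg in c(9, 7, 5)) {
    obj <- tryCatch({
      sol <- kernlab::ipop(c = matrix(rep(-1, n)), H = Q,
                           A = t(matrix(y)), b = 0,
                           l = matrix(rep(0, n)), u = matrix(rep(C, n)),
                           r = 0, sigf = sg, maxiter = 100)
      a <- kernlab::primal(sol)
      sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
    }, error = function(e) NA_real_)
    if (!is.na(obj)) return(obj)
  }
  NA_real_
}

# random separable-ish binary problem for solver checks
rand_svm_problem <- function(seed, n_range = 6:20, p_range = 2:5) {
  set.seed(seed)
  n <- sample(n_range, 1); p <- sample(p_range, 1)
  X <- matrix(rnorm(n * p), n)
  y <- sample(c(-1, 1), n, replace = TRUE)
  while (length(unique(y)) < 2) y <- sample(c(-1, 1), n, replace = TRUE)
  X[y > 0, 1] <- X[y > 0, 1] + 1
  list(X = X, y = y, C = sample(c(0.25, 1, 4), 1))
}

# KKT conditions of the dual solution at tolerance tol
kkt_violations <- function(fit, K, tol = 1e-4) {
  g <- drop(K %*% fit$coef) + fit$bias
  yg <- fit$y * g
  a <- fit$alpha; C <- fit$C
  at0 <- a <= 1e-8 * C
  atC <- a >= C * (1 - 1e-8)
  free <- !at0 & !atC
  c(lower = sum(yg[at0] < 1 - tol),
    free = sum(abs(yg[free] - 1) > tol),
    upper = sum(yg[atC] > 1 + tol))
}

null_phantom_spec <- function() {
  phantom_spec(group_effects = data.frame(group = character(0),
                                          region = character(0),
                                          factor = numeric(0)))
}
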