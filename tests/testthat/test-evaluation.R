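test_that("stratified folds balance sizes and classes", {
  labels <- rep(c("PD", "MSA", "PSP"), c(39, 24, 24))  # the study cohort
  f <- stratified_kfold(labels, k = 10, seed = 1)
  expect_length(f, 87)
  sizes <- table(f)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(sizes %in% c(8, 9)))   # 87 = 7x9 + 3x8
  for (cl in unique(labels)) {
    per <- table(factor(f[labels == cl], levels = 1:10))
    expect_lte(diff(range(per)), 1)
  }
  # every subject appears in exactly one test fold
  expect_equal(sort(unlist(lapply(1:10, function(i) which(f == i)))), 1:87)

  expect_identical(stratified_kfold(labels, 10, seed = 4),
                   stratified_kfold(labels, 10, seed = 4))
  expect_false(identical(stratified_kfold(labels, 10, seed = 4),
                         stratified_kfold(labels, 10, seed = 5)))
  # leave-one-out limit
  lab6 <- rep(c("a", "b"), 3)
  expect_equal(sort(suppressWarnings(stratified_kfold(lab6, 6, seed = 1))),
               1:6)
  expect_error(stratified_kfold(lab6, 7), "exceed")
  expect_warning(stratified_kfold(rep(c("a", "b"), c(10, 2)), 5, seed = 1),
                 "relaxed")
})

test_that("simplex grids enumerate the weight lattice exhaustively", {
  g2 <- enumerate_simplex_grid(2, 0.1)
  expect_length(g2, 9)
  expect_equal(g2[[1]], c(0.1, 0.9))
  expect_equal(g2[[9]], c(0.9, 0.1))
  g5 <- enumerate_simplex_grid(5, 0.1)
  expect_length(g5, 126)                       # C(9, 4) compositions
  expect_true(all(vapply(g5, function(q) abs(sum(q) - 1) < 1e-12,
                         logical(1))))
  expect_true(all(vapply(g5, function(q) all(q >= 0.1 - 1e-12),
                         logical(1))))
  expect_false(anyDuplicated(vapply(g5, paste, character(1),
                                    collapse = ",")) > 0)
  expect_equal(enumerate_simplex_grid(1, 0.1), list(1.0))
  expect_error(enumerate_simplex_grid(11, 0.1), "infeasible")
  expect_error(enumerate_simplex_grid(2, 0.3), "divide")
})

test_that("metrics count accuracy, sensitivity and specificity", {
  m <- metrics(c("p", "p", "n", "n"), c("p", "n", "n", "n"),
               positive = "p")
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)

  perfect <- metrics(rep(c("p", "n"), 4), rep(c("p", "n"), 4), "p")
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1))

  mc <- metrics(c("a", "a", "b", "c"), c("a", "b", "b", "b"))
  expect_equal(mc$accuracy, 0.5)
  expect_equal(mc$per_class, c(a = 0.5, b = 1, c = 0))
  expect_error(metrics(c("a", "a"), c("a", "a"), positive = "b"),
               "absent")
  expect_error(metrics(character(0), character(0)), "empty")
})

test_that("grid search honours candidate order only through the tie rule", {
  set.seed(3)
  X1 <- matrix(rnorm(40), 20); X2 <- matrix(rnorm(40), 20)
  y <- rep(c(-1, 1), 10)
  X1[y > 0, ] <- X1[y > 0, ] + 2          # block 1 is informative
  kernels <- list(tcrossprod(X1), tcrossprod(X2))

  # single candidate comes straight back
  gs1 <- grid_search(kernels, y, C_grid = 2, q_step = 0.5, inner_k = 2)
  expect_equal(gs1$C, 2)
  expect_equal(gs1$q, c(0.5, 0.5))
  expect_equal(gs1$n_candidates, 1L)

  gs <- grid_search(kernels, y, C_grid = c(1, 4), q_step = 0.2,
                    inner_k = 4, seed = 11)
  expect_true(gs$C %in% c(1, 4))
  expect_equal(sum(gs$q), 1, tolerance = 1e-12)
  gs_rep <- grid_search(kernels, y, C_grid = c(4, 1), q_step = 0.2,
                        inner_k = 4, seed = 11)
  expect_equal(gs_rep[c("C", "q")], gs[c("C", "q")])  # order-invariant

  # a flat landscape falls back to smallest C, lexicographically first q
  Kz <- matrix(0, 20, 20)
  flat <- grid_search(list(Kz, Kz), y, C_grid = c(8, 2), q_step = 0.5,
                      inner_k = 2, seed = 1)
  expect_equal(flat$C, 2)
  expect_equal(flat$q, c(0.5, 0.5))
  expect_error(grid_search(kernels, rep(1, 20), C_grid = 1, q_step = 0.5),
               "degenerate")
})

test_that("permutation p-values hit the documented boundaries", {
  # statistic ignores labels except for a flag planted in the first slot
  stat_hi <- function(lab) if (lab[1] == "x") 1 else 0
  labs <- c("x", rep("a", 9), rep("b", 10))
  res <- permutation_test(stat_hi, labs, n_perm = 50, seed = 2)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 0.1)          # ties only when "x" lands first
  stat_const <- function(lab) 0.5
  res2 <- permutation_test(stat_const, labs, n_perm = 25, seed = 1)
  expect_equal(res2$p_value, 1)         # every null >= observed
  stat_lo <- function(lab) if (lab[1] == "x") -1 else 0
  res3 <- permutation_test(stat_lo, labs, n_perm = 50, seed = 3)
  expect_equal(res3$observed, -1)
  expect_equal(res3$p_value, 1)
  # strictly-above-null observed: plain estimator 0, +1 correction 1/(m+1)
  labs1 <- c("x", "a", "a", "a", "a", "a")
  stat_first <- function(lab) as.numeric(lab[1] == "x") * 2 - 1
  set.seed(4)
  res4 <- permutation_test(stat_first, labs1, n_perm = 20, seed = 8)
  if (all(res4$null < res4$observed)) {
    expect_equal(res4$p_value, 0)
    res5 <- permutation_test(stat_first, labs1, n_perm = res4$n_perm,
                             seed = 8, plus_one = TRUE)
    expect_equal(res5$p_value, 1 / (res4$n_perm + 1))
  }
  expect_error(permutation_test(stat_const, labs, n_perm = 0), "at least 1")
})

test_that("ROC curves match the Mann-Whitney pairwise count", {
  # toy cases
  expect_equal(roc_curve(c(1, 2, 3, 4), c("n", "n", "p", "p"), "p")$auc, 1)
  expect_equal(roc_curve(c(4, 3, 2, 1), c("n", "n", "p", "p"), "p")$auc, 0)
  expect_equal(roc_curve(rep(2, 6), rep(c("n", "p"), 3), "p")$auc, 0.5)

  brute_auc <- function(scores, pos) {
    sp <- scores[pos]; sn <- scores[!pos]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:50, 1)
    scores <- round(rnorm(n), 1)           # rounding forces ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    rc <- roc_curve(scores, ifelse(pos, "p", "n"), "p")
    expect_equal(rc$auc, brute_auc(scores, pos), tolerance = 1e-12)
    # monotone curve from (0,0) to (1,1)
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]),
                 c(1, 1))
    expect_true(all(diff(rc$fpr) >= 0))
    expect_true(all(diff(rc$tpr) >= 0))
  }
  expect_error(roc_curve(1:3, c("p", "p", "p"), "p"), "both classes")
})

test_that("pooled t-maps match the textbook formula", {
  mkvols <- function(mat) apply(mat, 1, function(row)
    volume(array(row, c(1, 1, 1))), simplify = FALSE)
  tm <- voxelwise_ttest(mkvols(matrix(c(1, 2, 3))),
                        mkvols(matrix(c(3, 4, 5))))
  expect_equal(tm$df, 4)
  expect_equal(tm$t$data[1], -2.449, tolerance = 1e-3)
  expect_equal(tm$t$data[1], -2 / sqrt(2 / 3), tolerance = 1e-12)
  # oracle: stats::t.test on random arrays, voxel by voxel
  set.seed(10)
  A <- lapply(1:4, function(i) rand_volume(c(3, 3, 2), seed = i))
  B <- lapply(1:5, function(i) rand_volume(c(3, 3, 2), seed = 50 + i))
  tm2 <- voxelwise_ttest(A, B)
  for (vx in sample(18, 5)) {
    av <- vapply(A, function(v) v$data[vx], numeric(1))
    bv <- vapply(B, function(v) v$data[vx], numeric(1))
    tt <- t.test(av, bv, var.equal = TRUE)
    expect_equal(tm2$t$data[vx], unname(tt$statistic), tolerance = 1e-10)
  }
  # z-scores preserve the tail probability
  expect_equal(pnorm(tm2$z$data[3], lower.tail = FALSE),
               pt(tm2$t$data[3], tm2$df, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("identical groups give a flat t-map and zero-variance flags", {
  v <- rand_volume(c(4, 4, 4), seed = 2)
  tm <- voxelwise_ttest(list(v, v, v), list(v, v, v))
  expect_true(all(tm$t$data == 0))
  expect_equal(nrow(tm$clusters), 0)
  expect_true(all(tm$undefined))
  expect_error(voxelwise_ttest(list(v), list(v, v)), "at least 2")
  expect_error(voxelwise_ttest(list(v, v),
                               list(rand_volume(c(3, 3, 3)),
                                    rand_volume(c(3, 3, 3)))),
               "mismatched")
})

test_that("cluster labelling uses 26-connectivity and mm^3 volumes", {
  m <- array(FALSE, c(5, 5, 5))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE    # touch only at a corner
  m[5, 5, 5] <- TRUE                        # far away
  cl <- label_clusters(m)
  expect_equal(max(cl), 2)
  expect_equal(cl[1, 1, 1], cl[2, 2, 2])    # diagonal neighbours join
  expect_true(cl[5, 5, 5] != cl[1, 1, 1])

  # cluster table volumes are count x voxel volume
  set.seed(33)
  A <- lapply(1:6, function(i) {
    d <- array(rnorm(4^3, 0, 0.1), c(4, 4, 4))
    d[1:2, 1:2, 1:2] <- d[1:2, 1:2, 1:2] + 5
    volume(d, c(2, 2, 2))
  })
  B <- lapply(7:12, function(i)
    volume(array(rnorm(4^3, 0, 0.1), c(4, 4, 4)), c(2, 2, 2)))
  tm <- voxelwise_ttest(A, B, p_thresh = 0.001)
  expect_gte(nrow(tm$clusters), 1)
  expect_equal(tm$clusters$volume_mm3, tm$clusters$n_voxels * 8)
  expect_equal(sum(tm$clusters$n_voxels), sum(tm$cluster_map > 0))
})
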