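toy_table <- function(n_l, n_h) {
  data.frame(group = c(rep("L", n_l), rep("H", n_h)))
}

test_that("stratified 70/30 split reproduces the per-group allocation arithmetic", {
  sp <- stratified_split(toy_table(14, 30), split_spec(seed = 5))
  expect_equal(sp$counts$train, c(10L, 21L))
  expect_equal(sp$counts$test, c(4L, 9L))
  sp2 <- stratified_split(toy_table(22, 19), split_spec(seed = 5))
  expect_equal(sp2$counts$train, c(15L, 13L))
  expect_equal(sp2$counts$test, c(7L, 6L))
  # disjoint cover of all rows
  expect_equal(sort(c(sp$train, sp$test)), 1:44)
  # deterministic given seed, different under another seed
  sp_b <- stratified_split(toy_table(14, 30), split_spec(seed = 5))
  expect_identical(sp$train, sp_b$train)
  expect_error(stratified_split(toy_table(1, 10)), "at least 2")
})

test_that("RBF-SVM separates distant clusters and solves XOR", {
  set.seed(41)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 10), ncol = 2))
  y <- rep(c("L", "H"), each = 20)
  m <- train_rbf_svm(x, y)
  expect_equal(mean(predict(m, x) == y), 1)
  # duplicating every training point leaves predictions unchanged
  m2 <- train_rbf_svm(rbind(x, x), c(y, y))
  expect_equal(as.character(predict(m2, x)), as.character(predict(m, x)))
  # XOR pattern requires the kernel nonlinearity
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  xor_y <- c("L", "H", "H", "L")
  mx <- train_rbf_svm(xor_x, xor_y, cost = 100, gamma = 1)
  expect_equal(as.character(predict(mx, xor_x)), xor_y)
  expect_error(train_rbf_svm(x[1:20, ], y[1:20]), "single class")
})

test_that("SVM decision values match the explicit kernel expansion", {
  set.seed(42)
  x <- rbind(matrix(rnorm(30, 0, 2), ncol = 2), matrix(rnorm(30, 3, 2), ncol = 2))
  y <- rep(c("L", "H"), each = 15)
  m <- train_rbf_svm(x, y, cost = 1, gamma = 0.5)
  # brute-force oracle: f(u) = sum_i alpha_i k(sv_i, u) - rho
  dec_oracle <- apply(x, 1, function(u) {
    k <- exp(-m$gamma * colSums((t(m$SV) - u)^2))
    sum(m$coefs * k) - m$rho
  })
  dec_model <- attr(predict(m, x, decision.values = TRUE), "decision.values")[, 1]
  expect_equal(unname(dec_oracle), unname(dec_model), tolerance = 1e-8)
})

test_that("RBF-SVM agrees with an independent implementation on separable data", {
  skip_if_not_installed("kernlab")
  set.seed(43)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
  y <- rep(c("L", "H"), each = 30)
  m <- train_rbf_svm(x, y, cost = 1, gamma = 0.5)
  k <- kernlab::ksvm(x, factor(y, levels = c("L", "H")), kernel = "rbfdot",
                     kpar = list(sigma = 0.5), C = 1, scaled = FALSE)
  expect_equal(as.character(predict(m, x)), as.character(kernlab::predict(k, x)))
})

test_that("confusion metrics follow their definitions", {
  truth <- c(rep("H", 9), rep("L", 4))
  pred <- c(rep("H", 7), "L", "L", "H", rep("L", 3))
  cm <- confusion_metrics(truth, pred)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(7, 2, 1, 3))
  expect_equal(cm$sensitivity, 7 / 9)
  expect_equal(cm$specificity, 3 / 4)
  expect_equal(cm$accuracy, 10 / 13)
  # metrics recompute from the stored counts
  expect_equal(cm$accuracy, (cm$tp + cm$tn) / sum(cm$matrix), tolerance = 1e-3)
  expect_equal(unname(rowSums(cm$normalized)), c(1, 1))
  # perfect predictions: accuracy 1, off-diagonal zeros
  cmp <- confusion_metrics(truth, truth)
  expect_equal(cmp$accuracy, 1)
  expect_equal(cmp$fn + cmp$fp, 0)
})

test_that("all-high classifier on an L14/H30 cohort scores the majority share", {
  truth <- c(rep("L", 14), rep("H", 30))
  cm <- confusion_metrics(truth, rep("H", 44))
  expect_equal(cm$accuracy, 30 / 44)
  expect_equal(round(100 * cm$accuracy, 1), 68.2)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0)
})

test_that("cv_result reports the arithmetic mean and sample sd of fold scores", {
  cv <- cv_result(c(66.7, 77.8, 77.8, 88.9, 75.0) / 100)
  expect_equal(round(100 * cv$mean, 1), 77.2)
  expect_equal(round(100 * cv$sd, 1), 7.9)
  expect_equal(cv$mean, mean(cv$fold_scores))
  expect_equal(cv$sd, sd(cv$fold_scores))
})

test_that("cross-validation uses each stratified fold exactly once", {
  set.seed(44)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 5), ncol = 2))
  y <- rep(c("L", "H"), each = 30)
  cv <- cross_validate(x, y, k = 5, seed = 2L)
  expect_length(cv$fold_scores, 5L)
  expect_equal(sort(unique(cv$folds)), 1:5)
  # stratification: every fold contains both classes
  for (f in 1:5) expect_setequal(unique(y[cv$folds == f]), c("L", "H"))
  expect_equal(cv$mean, mean(cv$fold_scores))
  # same seed, same folds
  cv2 <- cross_validate(x, y, k = 5, seed = 2L)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$fold_scores, cv2$fold_scores)
  expect_error(cross_validate(x[1:4, ], y[c(1, 2, 31, 32)], k = 5), "exceeds")
  # well-separated data cross-validates near-perfectly
  expect_gte(cv$mean, 0.95)
})

test_that("PCA fusion standardizes, fixes signs and preserves low-rank structure", {
  set.seed(45)
  # rank-2 case: two duplicated columns reproduce the 2-D structure
  a <- rnorm(50); b <- rnorm(50)
  fus <- pca_fuse(cbind(a, b), cbind(a, b))
  expect_equal(sum(fus$explained_variance), 1, tolerance = 1e-10)
  # distances preserved when only 2 nonzero eigenvalues exist
  d_orig <- dist(scale(cbind(a, b, a, b)))
  d_proj <- dist(fus$scores)
  expect_equal(as.numeric(d_proj), as.numeric(d_orig), tolerance = 1e-8)
  # sign convention: largest-magnitude loading entry is positive
  expect_true(all(apply(fus$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  # 4 independent equal-variance columns: top-2 capture ~50%
  x4 <- matrix(rnorm(4 * 3000), ncol = 4)
  fus4 <- pca_fuse(x4[, 1:2], x4[, 3:4])
  expect_equal(sum(fus4$explained_variance), 0.5, tolerance = 0.05)
  expect_error(pca_fuse(cbind(a, rep(1, 50)), cbind(b, b + 1)), "zero-variance")
})

test_that("decision-boundary grids agree with model predictions and refine consistently", {
  set.seed(46)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 6), ncol = 2))
  y <- rep(c("L", "H"), each = 20)
  m <- train_rbf_svm(x, y)
  bounds <- list(c(-3, 9), c(-3, 9))
  g <- decision_boundary_grid(m, bounds = bounds, resolution = 11)
  # grid predictions match direct model predictions
  direct <- as.character(predict(m, as.matrix(g[, c("x1", "x2")])))
  expect_equal(g$label, direct)
  # doubling resolution never contradicts shared grid points
  g2 <- decision_boundary_grid(m, bounds = bounds, resolution = 21)
  key <- function(d) paste(round(d$x1, 9), round(d$x2, 9))
  shared <- match(key(g), key(g2))
  expect_false(anyNA(shared))
  expect_equal(g$label, g2$label[shared])
})
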