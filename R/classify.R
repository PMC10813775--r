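# Stratified splitting, RBF-SVM training, confusion-matrix metrics,
# stratified 5-fold cross-validation and PCA fusion with clinical covariates.
# The high-severity group (H) is the positive class throughout.

#' Train/test split specification
#'
#' @param train_fraction Fraction of each group assigned to training; the
#'   per-group training count is `round(train_fraction * group size)`
#'   (round-half-to-even).
#' @param seed RNG seed for the random assignment.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 strategy = "stratified_by_group"),
            class = "split_spec")
}

#' Stratified train/test split
#'
#' Randomly assigns rows to training and testing within each severity group,
#' preserving the group proportions: a group of size `n` contributes
#' `round(train_fraction * n)` training rows. With the canonical 70% fraction
#' this reproduces the per-cell allocation used for the cohorts L14/H30
#' (train 10/21, test 4/9) and L22/H19 (train 15/13, test 7/6).
#'
#' @param table A [feature_table()] data frame with a `group` column.
#' @param spec A [split_spec()].
#' @return A list with integer vectors `train` and `test` (disjoint, jointly
#'   covering all rows) and a `counts` table of per-group allocations.
#' @export
stratified_split <- function(table, spec = split_spec()) {
  groups <- table$group
  if (any(table(groups) < 2)) {
    stop("each severity group needs at least 2 subjects to split", call. = FALSE)
  }
  train <- integer(0)
  with_seed(spec$seed, {
    for (g in c("L", "H")) {
      idx <- which(groups == g)
      n_train <- round(spec$train_fraction * length(idx))
      train <- c(train, sample(idx, n_train))
    }
  })
  train <- sort(train)
  test <- setdiff(seq_len(nrow(table)), train)
  counts <- data.frame(
    group = c("L", "H"),
    total = c(sum(groups == "L"), sum(groups == "H")),
    train = c(sum(groups[train] == "L"), sum(groups[train] == "H")),
    test = c(sum(groups[test] == "L"), sum(groups[test] == "H"))
  )
  list(train = train, test = test, counts = counts, spec = spec)
}

#' Train an RBF-kernel support vector machine
#'
#' Maximum-margin classifier with the radial basis function kernel
#' `k(u, v) = exp(-gamma * ||u - v||^2)`, fitted with [e1071::svm()]. The
#' default kernel width follows the variance-scaled heuristic
#' `gamma = 1 / (n_features * var(X))`; features entering the model are
#' already min-max normalized, so no further scaling is applied.
#'
#' @param x Numeric feature matrix (rows = subjects).
#' @param y Group labels (`"L"`/`"H"`), both classes present.
#' @param cost Soft-margin penalty C.
#' @param gamma Kernel width; `NULL` for the variance-scaled default.
#' @param class_weights Optional named class weights (e.g. inverse class
#'   frequencies); `NULL` for the unweighted fit.
#' @return The fitted `svm` object with the training call's `gamma` stored.
#' @export
train_rbf_svm <- function(x, y, cost = 1, gamma = NULL, class_weights = NULL) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("L", "H"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training labels contain a single class; cannot fit a classifier",
         call. = FALSE)
  }
  if (!all(is.finite(x))) stop("feature matrix must be finite", call. = FALSE)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE,
             class.weights = class_weights)
}

#' Confusion matrix and accuracy metrics
#'
#' Tabulates predictions against truth with the high-severity class as
#' positive, and derives accuracy, sensitivity (true-positive rate for H)
#' and specificity (true-negative rate for L). The row-normalized matrix
#' divides each true-class row by its row sum.
#'
#' @param truth,predicted Label vectors (`"L"`/`"H"`).
#' @return An object of class `confusion` with `tp`, `fn`, `fp`, `tn`,
#'   `accuracy`, `sensitivity`, `specificity`, `matrix` (counts) and
#'   `normalized` (row-proportions).
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- factor(truth, levels = c("L", "H"))
  predicted <- factor(predicted, levels = c("L", "H"))
  tp <- sum(truth == "H" & predicted == "H")
  fn <- sum(truth == "H" & predicted == "L")
  fp <- sum(truth == "L" & predicted == "H")
  tn <- sum(truth == "L" & predicted == "L")
  m <- matrix(c(tn, fp, fn, tp), nrow = 2, byrow = TRUE,
              dimnames = list(truth = c("L", "H"), predicted = c("L", "H")))
  rs <- rowSums(m)
  normalized <- sweep(m, 1, ifelse(rs == 0, 1, rs), "/")
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn,
         accuracy = (tp + tn) / length(truth),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         matrix = m, normalized = normalized),
    class = "confusion"
  )
}

#' @export
print.confusion <- function(x, ...) {
  cat("Confusion matrix (positive class = H):\n")
  print(x$matrix)
  cat(sprintf("accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Evaluate a fitted classifier
#'
#' @param model A fitted `svm` (or any model with a `predict` method
#'   returning `"L"`/`"H"`).
#' @param x Feature matrix.
#' @param y True labels.
#' @return A list with `accuracy` and the full [confusion_metrics()] object.
#' @export
evaluate_model <- function(model, x, y) {
  pred <- stats::predict(model, as.matrix(x))
  cm <- confusion_metrics(y, pred)
  list(accuracy = cm$accuracy, confusion = cm, predictions = as.character(pred))
}

#' Cross-validation result from fold accuracies
#'
#' Bookkeeping container: the mean is the arithmetic mean of the fold
#' accuracies, the dispersion the sample standard deviation — e.g. fold
#' scores (66.7, 77.8, 77.8, 88.9, 75.0) give 77.2 +/- 7.9 (percent).
#'
#' @param fold_scores Numeric vector of per-fold accuracies.
#' @return An object of class `cv_result` with `fold_scores`, `mean`, `sd`.
#' @export
cv_result <- function(fold_scores) {
  structure(list(fold_scores = fold_scores,
                 mean = mean(fold_scores),
                 sd = stats::sd(fold_scores)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  k <- length(x$fold_scores)
  cat(sprintf("%d-fold cross-validation: %s\n", k,
              paste(sprintf("%.1f", 100 * x$fold_scores), collapse = " ")))
  cat(sprintf("mean %.1f%% +/- %.1f%%\n", 100 * x$mean, 100 * x$sd))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffle and deal round-robin
# so every fold holds both classes whenever sizes allow.
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (g in unique(y)) {
      idx <- sample(which(y == g))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the RBF-SVM
#'
#' Splits the data into `k` stratified folds; each fold serves once as the
#' validation set while the remaining folds train the classifier. Reports
#' the per-fold accuracies and their mean +/- sample SD.
#'
#' @param x Feature matrix.
#' @param y Labels (`"L"`/`"H"`).
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param cost,gamma,class_weights Passed to [train_rbf_svm()].
#' @return A [cv_result()] with an additional `folds` element (fold id per
#'   row).
#' @export
cross_validate <- function(x, y, k = 5, seed = 1L, cost = 1, gamma = NULL,
                           class_weights = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop(sprintf("k = %d exceeds sample size %d", k, n), call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("cross-validation requires both classes", call. = FALSE)
  }
  folds <- stratified_folds(y, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    model <- train_rbf_svm(x[tr, , drop = FALSE], y[tr], cost = cost,
                           gamma = gamma, class_weights = class_weights)
    mean(stats::predict(model, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  out <- cv_result(scores)
  out$folds <- folds
  out
}

#' Fuse NIRS features with clinical covariates by PCA
#'
#' Standardizes the two selected NIRS features together with age and BMI
#' (zero mean, unit variance) and projects onto the top two principal
#' components, reducing the four-dimensional fused feature space back to the
#' two dimensions the classifier consumes. Component signs are fixed by
#' making each loading vector's largest-magnitude entry positive, so the
#' projection is deterministic.
#'
#' @param nirs Two-column matrix of selected NIRS features.
#' @param clinical Two-column matrix (age, BMI).
#' @return A list with `scores` (n x 2 matrix `PC1`, `PC2`), `loadings`
#'   (4 x 2), `center`, `scale` and `explained_variance` (fractions).
#' @export
pca_fuse <- function(nirs, clinical) {
  x <- cbind(as.matrix(nirs), as.matrix(clinical))
  if (ncol(x) != 4L) stop("expected 2 NIRS + 2 clinical columns", call. = FALSE)
  if (nrow(x) < 3L) stop("PCA fusion needs at least 3 subjects", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ", paste(colnames(x)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- scale(x, center = pc$center, scale = pc$scale) %*% rot
  colnames(scores) <- c("PC1", "PC2")
  list(scores = scores, loadings = rot, center = pc$center, scale = pc$scale,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[1:2])
}

# Apply a stored PCA fusion to new data (same column order as at fit time).
pca_apply <- function(fusion, nirs, clinical) {
  x <- cbind(as.matrix(nirs), as.matrix(clinical))
  scores <- scale(x, center = fusion$center, scale = fusion$scale) %*% fusion$loadings
  colnames(scores) <- c("PC1", "PC2")
  scores
}

#' Decision-boundary grid for a 2-D classifier
#'
#' Evaluates the fitted classifier on a dense rectangular grid, for
#' decision-boundary plots.
#'
#' @param model A fitted 2-feature classifier.
#' @param bounds List or matrix giving `(min, max)` per feature; defaults to
#'   the training range expanded by 10%.
#' @param resolution Grid points per axis.
#' @param x Optional training matrix used to derive default bounds.
#' @return A data frame with grid coordinates `x1`, `x2` and the predicted
#'   `label`.
#' @export
decision_boundary_grid <- function(model, bounds = NULL, resolution = 100, x = NULL) {
  if (is.null(bounds)) {
    if (is.null(x)) stop("supply `bounds` or the training matrix `x`", call. = FALSE)
    r1 <- range(x[, 1]); r2 <- range(x[, 2])
    pad1 <- 0.1 * diff(r1); pad2 <- 0.1 * diff(r2)
    bounds <- list(c(r1[1] - pad1, r1[2] + pad1), c(r2[1] - pad2, r2[2] + pad2))
  }
  g1 <- seq(bounds[[1]][1], bounds[[1]][2], length.out = resolution)
  g2 <- seq(bounds[[2]][1], bounds[[2]][2], length.out = resolution)
  grid <- as.matrix(expand.grid(x1 = g1, x2 = g2))
  pred <- stats::predict(model, grid)
  data.frame(x1 = grid[, 1], x2 = grid[, 2], label = as.character(pred),
             stringsAsFactors = FALSE)
}
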