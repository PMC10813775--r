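#' Fit the severity-classification model
#'
#' The central fitting routine: from a cohort feature table it (1) draws a
#' stratified 70/30 train/test split, (2) screens all features by
#' independent-samples t-tests on the training rows only, (3) selects the two
#' top-ranked significant NIRS features (or uses `features` if supplied),
#' (4) optionally fuses them with age and BMI through PCA down to two
#' dimensions, (5) trains an RBF-kernel SVM on the training rows, and
#' (6) evaluates train/test accuracy, the confusion matrix (positive class =
#' high severity) and stratified 5-fold cross-validation on the training set.
#'
#' @param table A [feature_table()] data frame.
#' @param features Optional character vector of two feature names to use,
#'   bypassing selection (screening is still reported).
#' @param with_clinical Fuse the NIRS features with age and BMI via
#'   [pca_fuse()] before classification.
#' @param split A [split_spec()].
#' @param variant t-test variant for screening.
#' @param n_features Number of NIRS features to select.
#' @param cost,gamma,class_weights SVM hyperparameters, see
#'   [train_rbf_svm()].
#' @param cv_folds Number of cross-validation folds (0 to skip CV).
#' @param cv_seed Seed for the CV fold assignment.
#'
#' @return An object of class `severity_fit` with components `model`
#'   (the fitted SVM), `screen` (screening table), `features` (names used),
#'   `split`, `fusion` (PCA details or NULL), `train`, `test` (each with
#'   accuracy and confusion), `cv` (a `cv_result` or NULL), `data` (the
#'   feature table) and the effective hyperparameters.
#'
#' @examples
#' \donttest{
#' cfg <- sim_config("VV", sampling_rate = 5, group_sizes = c(14, 30), seed = 7)
#' tab <- feature_table(simulate_cohort(cfg))
#' fit <- fit_severity(tab)
#' print(fit)
#' }
#' @export
fit_severity <- function(table, features = NULL, with_clinical = FALSE,
                         split = split_spec(), variant = "pooled",
                         n_features = 2, cost = 1, gamma = NULL,
                         class_weights = NULL, cv_folds = 5, cv_seed = NULL) {
  sp <- stratified_split(table, split)
  screen <- screen_features(table, sp$train, variant = variant)
  if (is.null(features)) {
    features <- select_top(screen, max_features = n_features)
    if (length(features) == 0L) {
      stop("no significant feature available; supply `features` explicitly",
           call. = FALSE)
    }
  }
  missing_f <- setdiff(features, names(table))
  if (length(missing_f)) {
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "), call. = FALSE)
  }

  nirs_all <- as.matrix(table[features])
  fusion <- NULL
  if (with_clinical) {
    fusion <- pca_fuse(nirs_all[sp$train, , drop = FALSE],
                       as.matrix(table[sp$train, c("age", "bmi")]))
    x_all <- matrix(NA_real_, nrow(table), 2,
                    dimnames = list(NULL, c("PC1", "PC2")))
    x_all[sp$train, ] <- fusion$scores
    x_all[sp$test, ] <- pca_apply(fusion, nirs_all[sp$test, , drop = FALSE],
                                  as.matrix(table[sp$test, c("age", "bmi")]))
  } else {
    x_all <- nirs_all
  }
  y <- table$group

  model <- train_rbf_svm(x_all[sp$train, , drop = FALSE], y[sp$train],
                         cost = cost, gamma = gamma,
                         class_weights = class_weights)
  train_eval <- evaluate_model(model, x_all[sp$train, , drop = FALSE], y[sp$train])
  test_eval <- evaluate_model(model, x_all[sp$test, , drop = FALSE], y[sp$test])
  cv <- NULL
  if (cv_folds > 0) {
    cv <- cross_validate(x_all[sp$train, , drop = FALSE], y[sp$train],
                         k = cv_folds,
                         seed = if (is.null(cv_seed)) split$seed else cv_seed,
                         cost = cost, gamma = model$gamma,
                         class_weights = class_weights)
  }
  structure(
    list(mode = if ("mode" %in% names(table)) table$mode[1] else NA_character_,
         model = model, screen = screen, features = features,
         with_clinical = with_clinical, fusion = fusion,
         split = sp, x = x_all, y = y,
         train = train_eval, test = test_eval, cv = cv,
         hyperparameters = list(cost = cost, gamma = model$gamma,
                                class_weights = class_weights),
         data = table),
    class = "severity_fit"
  )
}

#' @export
print.severity_fit <- function(x, ...) {
  cat(sprintf("RBF-SVM severity model (%s mode%s)\n", x$mode,
              if (x$with_clinical) ", NIRS + clinical PCA fusion" else ""))
  cat("features: ", paste(x$features, collapse = ", "), "\n", sep = "")
  cat(sprintf("train accuracy %.1f%% (n = %d) | test accuracy %.1f%% (n = %d)\n",
              100 * x$train$accuracy, length(x$split$train),
              100 * x$test$accuracy, length(x$split$test)))
  if (!is.null(x$cv)) {
    cat(sprintf("%d-fold CV: mean %.1f%% +/- %.1f%%\n",
                length(x$cv$fold_scores), 100 * x$cv$mean, 100 * x$cv$sd))
  }
  invisible(x)
}

#' @export
summary.severity_fit <- function(object, ...) {
  cat(sprintf("RBF-SVM severity classification, %s mode\n", object$mode))
  cat(sprintf("cohort: %d subjects (%d L / %d H); train %d / test %d\n",
              nrow(object$data), sum(object$y == "L"), sum(object$y == "H"),
              length(object$split$train), length(object$split$test)))
  cat(sprintf("hyperparameters: C = %g, gamma = %g\n",
              object$hyperparameters$cost, object$hyperparameters$gamma))
  cat("\nTop screened features (training rows only):\n")
  top <- utils::head(object$screen[, c("feature", "p_value", "significance")], 8)
  top$p_value <- signif(top$p_value, 3)
  print(top, row.names = FALSE)
  cat("\nSelected features:", paste(object$features, collapse = ", "), "\n")
  if (object$with_clinical) {
    cat("PCA fusion loadings (features + age, bmi):\n")
    print(round(object$fusion$loadings, 3))
    cat(sprintf("explained variance: %.1f%% + %.1f%%\n",
                100 * object$fusion$explained_variance[1],
                100 * object$fusion$explained_variance[2]))
  }
  cat("\nTest-set performance:\n")
  print(object$test$confusion)
  if (!is.null(object$cv)) print(object$cv)
  invisible(object)
}

#' Predict severity group for new subjects
#'
#' @param object A [fit_severity()] model.
#' @param newdata A data frame carrying the model's feature columns (and
#'   `age`/`bmi` when the model was fitted with clinical fusion); defaults to
#'   the training table.
#' @param ... Unused.
#' @return Character vector of predicted groups (`"L"`/`"H"`).
#' @export
predict.severity_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(as.character(stats::predict(object$model, object$x)))
  }
  nirs <- as.matrix(newdata[object$features])
  x <- if (object$with_clinical) {
    pca_apply(object$fusion, nirs, as.matrix(newdata[, c("age", "bmi")]))
  } else {
    nirs
  }
  as.character(stats::predict(object$model, x))
}

#' Plot the 2-D decision boundary of a fitted severity model
#'
#' Shades the feature plane by predicted class and overlays the training
#' (circles) and test (triangles) subjects, low severity in red and high in
#' blue, in the style of a two-feature SVM decision plot.
#'
#' @param x A [fit_severity()] object.
#' @param resolution Grid points per axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.severity_fit <- function(x, resolution = 150, ...) {
  grid <- decision_boundary_grid(x$model, x = x$x, resolution = resolution)
  cols <- c(L = "#fdd5d5", H = "#d0dcf5")
  pt_cols <- c(L = "#c0392b", H = "#2e4a9e")
  labs <- if (x$with_clinical) c("PC1", "PC2") else x$features
  graphics::plot(grid$x1, grid$x2, col = cols[grid$label], pch = 15, cex = 0.6,
                 xlab = labs[1], ylab = labs[2],
                 main = sprintf("%s severity decision boundary", x$mode), ...)
  pch <- ifelse(seq_len(nrow(x$x)) %in% x$split$train, 21, 24)
  graphics::points(x$x[, 1], x$x[, 2], bg = pt_cols[x$y], pch = pch)
  graphics::legend("topright", bty = "n",
                   legend = c("L train", "H train", "L test", "H test"),
                   pt.bg = pt_cols[c("L", "H", "L", "H")],
                   pch = c(21, 21, 24, 24))
  invisible(x)
}
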