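# Univariate feature screening with independent-samples t-tests, run on
# training rows only so selection never sees the held-out test data.

#' Two-sample t-test for one feature
#'
#' Two-sided independent-samples t-test between the low- and high-severity
#' groups. The default is the pooled-variance (Student) variant; Welch's
#' unequal-variance form is available. The sign convention is
#' `t = (mean_L - mean_H) / se`, so swapping the groups flips `t` and leaves
#' `p` unchanged. When both groups are constant (zero variance) the test is
#' degenerate: `t = 0, p = 1` is returned with a warning.
#'
#' @param values_l,values_h Numeric samples for the two groups (each n >= 2).
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @return A list with `t`, `p`, `mean_l`, `mean_h`, `n_l`, `n_h`.
#' @export
ttest_feature <- function(values_l, values_h, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(values_l) < 2L || length(values_h) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (!all(is.finite(values_l)) || !all(is.finite(values_h))) {
    stop("feature values must be finite", call. = FALSE)
  }
  base <- list(mean_l = mean(values_l), mean_h = mean(values_h),
               n_l = length(values_l), n_h = length(values_h))
  if (stats::var(values_l) == 0 && stats::var(values_h) == 0) {
    warning("zero variance in both groups; t-test degenerate (p = 1)",
            call. = FALSE)
    return(c(list(t = 0, p = 1), base))
  }
  tt <- stats::t.test(values_l, values_h, var.equal = (variant == "pooled"))
  c(list(t = unname(tt$statistic), p = tt$p.value), base)
}

significance_stars <- function(p) {
  ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))
}

#' Screen features on the training rows of a feature table
#'
#' Runs [ttest_feature()] for every NIRS feature column and for the clinical
#' covariates (age, BMI), using only the rows in `train_indices`, and returns
#' the results sorted by ascending p-value (ties broken by feature name, for
#' determinism). Significance flags follow the usual convention:
#' `**` for p <= 0.01, `*` for 0.01 < p <= 0.05.
#'
#' @param table A [feature_table()] data frame.
#' @param train_indices Row indices of the training split; defaults to all
#'   rows.
#' @param variant t-test variant, see [ttest_feature()].
#' @param include_clinical Also test `age` and `bmi`.
#' @return A data frame sorted by p: `feature`, `t_stat`, `p_value`,
#'   `significance`, `mean_L`, `mean_H`, `n_L`, `n_H`, `is_clinical`.
#' @export
screen_features <- function(table, train_indices = seq_len(nrow(table)),
                            variant = c("pooled", "welch"),
                            include_clinical = TRUE) {
  variant <- match.arg(variant)
  train <- table[train_indices, , drop = FALSE]
  groups <- unique(train$group)
  if (!all(c("L", "H") %in% groups)) {
    stop("training rows must contain both severity groups", call. = FALSE)
  }
  cols <- feature_names(table)
  clinical <- if (include_clinical) c("age", "bmi") else character(0)
  res <- lapply(c(cols, clinical), function(f) {
    r <- ttest_feature(train[[f]][train$group == "L"],
                       train[[f]][train$group == "H"], variant)
    data.frame(feature = f, t_stat = r$t, p_value = r$p,
               significance = significance_stars(r$p),
               mean_L = r$mean_l, mean_H = r$mean_h,
               n_L = r$n_l, n_H = r$n_h,
               is_clinical = f %in% clinical,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-ranked significant NIRS features
#'
#' Keeps the at most `max_features` NIRS (non-clinical) features with the
#' smallest p-values among those with `p <= alpha`. The default of two
#' features matches the two-dimensional models used downstream. Returns an
#' empty vector with a warning when nothing is significant.
#'
#' @param results A [screen_features()] data frame (already sorted by p).
#' @param max_features Maximum number of features to keep.
#' @param alpha Significance threshold.
#' @return Character vector of selected feature names.
#' @export
select_top <- function(results, max_features = 2, alpha = 0.05) {
  pool <- results[!results$is_clinical & results$p_value <= alpha, , drop = FALSE]
  if (nrow(pool) == 0L) {
    warning("no feature passes the significance threshold; empty selection",
            call. = FALSE)
    return(character(0))
  }
  utils::head(pool$feature, max_features)
}
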