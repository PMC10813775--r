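# Stage-based feature families.
#
# Four families over the six protocol stages, computed on the filtered and
# normalized channels:
#   SM  stage mean        6 stages x 4 signals (HbO2, HHb, HBT, TSI)  = 24
#   SA  stage activation  5 task stages x 3 Hb signals                 = 15
#   SD  stage difference  5 task stages x 3 Hb signals                 = 15
#   SS  stage slope       6 stages x 3 Hb signals                      = 18
# Total 72; SA and SD coincide at Stage1 (both are Stage1 mean minus the
# baseline mean), so 3 duplicates are dropped, leaving 69.

#' Per-stage arithmetic means
#'
#' @param x Channel series.
#' @param segments Stage segmentation from [segment_recording()].
#' @return Named numeric vector, one mean per stage.
#' @export
stage_mean <- function(x, segments) {
  out <- vapply(seq_len(nrow(segments)),
                function(k) mean(segment_slice(x, segments[k, ])),
                numeric(1))
  names(out) <- segments$label
  out
}

#' Stage activation: stage mean minus baseline mean
#'
#' @inheritParams stage_mean
#' @return Named vector over Stage1..Stage5.
#' @export
stage_activation <- function(x, segments) {
  m <- stage_mean(x, segments)
  out <- m[-1L] - m[[1L]]
  names(out) <- segments$label[-1L]
  out
}

#' Stage difference: stage mean minus previous-stage mean
#'
#' The predecessor of Stage1 is the baseline, so the Stage1 difference equals
#' the Stage1 activation — the structural identity behind the three duplicate
#' features.
#'
#' @inheritParams stage_mean
#' @return Named vector over Stage1..Stage5.
#' @export
stage_difference <- function(x, segments) {
  m <- stage_mean(x, segments)
  out <- diff(m)
  names(out) <- segments$label[-1L]
  out
}

#' Per-stage temporal slope
#'
#' Slope of the channel within each stage, in normalized units per second.
#' `least_squares` (default) fits an ordinary least-squares line against
#' time; `endpoints` uses the first-to-last sample difference divided by the
#' elapsed time.
#'
#' @inheritParams stage_mean
#' @param sampling_rate Sampling rate in Hz.
#' @param method `"least_squares"` or `"endpoints"`.
#' @return Named vector, one slope per stage.
#' @export
stage_slope <- function(x, segments, sampling_rate,
                        method = c("least_squares", "endpoints")) {
  method <- match.arg(method)
  out <- vapply(seq_len(nrow(segments)), function(k) {
    y <- segment_slice(x, segments[k, ])
    if (length(y) < 2L) {
      stop(sprintf("stage %s has fewer than 2 samples; slope undefined",
                   segments$label[k]), call. = FALSE)
    }
    t_s <- (seq_along(y) - 1L) / sampling_rate
    if (method == "least_squares") {
      tc <- t_s - mean(t_s)
      sum(tc * y) / sum(tc^2)
    } else {
      (y[length(y)] - y[1L]) / (t_s[length(t_s)] - t_s[1L])
    }
  }, numeric(1))
  names(out) <- segments$label
  out
}

# Signal name as used in feature labels (total hemoglobin appears as "HBT").
feature_signal_names <- c(HbO2 = "HbO2", HHb = "HHb", HbT = "HBT", TSI = "TSI")

#' Extract the stage-based feature vector from a preprocessed recording
#'
#' Assembles the four feature families into one named vector with labels
#' `{family}_{signal}_{stage}`. With `deduplicate = TRUE` (default) the three
#' Stage1 stage-difference features — identical to the Stage1 activations —
#' are dropped, yielding the canonical 69 features; with `FALSE` all 72 are
#' returned.
#'
#' @param recording A preprocessed `nirs_recording` with channels `HbO2`,
#'   `HHb`, `HbT`, `TSI`.
#' @param slope_method Slope estimator passed to [stage_slope()].
#' @param deduplicate Drop the duplicated Stage1 stage-difference features.
#' @param keep Which of the duplicated pair to keep, `"SA"` (default) or
#'   `"SD"`; the dropped family's Stage1 entries are removed.
#' @return Named numeric vector of 69 (or 72) features, deterministic order:
#'   families SM, SA, SD, SS; within family, signals HbO2, HHb, HBT (TSI
#'   last, SM only); stages in protocol order.
#' @export
extract_features <- function(recording, slope_method = "least_squares",
                             deduplicate = TRUE, keep = c("SA", "SD")) {
  keep <- match.arg(keep)
  need <- c("HbO2", "HHb", "HbT", "TSI")
  missing_ch <- setdiff(need, names(recording$channels))
  if (length(missing_ch)) {
    stop("recording is missing channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  segments <- segment_recording(recording$n_samples, recording$sampling_rate,
                                recording$protocol)
  hb_signals <- c("HbO2", "HHb", "HbT")
  out <- numeric(0)
  add <- function(out, family, signal, values) {
    names(values) <- sprintf("%s_%s_%s", family, feature_signal_names[[signal]],
                             names(values))
    c(out, values)
  }
  for (sig in need) {
    out <- add(out, "SM", sig, stage_mean(recording$channels[[sig]], segments))
  }
  for (sig in hb_signals) {
    out <- add(out, "SA", sig, stage_activation(recording$channels[[sig]], segments))
  }
  for (sig in hb_signals) {
    out <- add(out, "SD", sig, stage_difference(recording$channels[[sig]], segments))
  }
  for (sig in hb_signals) {
    out <- add(out, "SS", sig,
               stage_slope(recording$channels[[sig]], segments,
                           recording$sampling_rate, slope_method))
  }
  if (deduplicate) {
    drop_family <- if (keep == "SA") "SD" else "SA"
    drop_names <- sprintf("%s_%s_Stage1", drop_family,
                          feature_signal_names[hb_signals])
    out <- out[setdiff(names(out), drop_names)]
  }
  out
}

#' Build a feature table for a cohort
#'
#' Preprocesses every recording and extracts its feature vector, returning a
#' rectangular table of 69 feature columns plus subject metadata — the input
#' to feature screening and classification.
#'
#' @param cohort A list of raw `nirs_recording`s (e.g. [simulate_cohort()]).
#' @param spec A [filter_spec()] applied to every recording.
#' @param ... Passed to [extract_features()].
#' @return A data frame: `subject_id`, `mode`, `group`, `apache_score`,
#'   `age`, `bmi`, then one column per feature.
#' @export
feature_table <- function(cohort, spec = filter_spec(), ...) {
  rows <- lapply(cohort, function(rec) {
    pp <- preprocess_recording(rec, spec)
    fv <- extract_features(pp, ...)
    cbind(
      data.frame(subject_id = rec$subject_id, mode = rec$mode,
                 group = rec$metadata$group,
                 apache_score = rec$metadata$apache_score,
                 age = rec$metadata$age, bmi = rec$metadata$bmi,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(fv), check.names = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out)) stop("feature table contains missing values", call. = FALSE)
  out
}

#' Names of the feature columns in a feature table
#' @param table A [feature_table()] data frame.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("subject_id", "mode", "group", "apache_score",
                          "age", "bmi"))
}
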