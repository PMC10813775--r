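#' Run configuration for the end-to-end pipeline
#'
#' One config drives the whole analysis: simulation, filtering, splitting,
#' screening and classification. All stage seeds derive from `seed`, so a
#' config fully determines every artifact. Configs round-trip losslessly
#' through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param mode `"VV"` or `"VA"`.
#' @param sim A [sim_config()]; built from `mode` and `seed` if omitted.
#' @param filter A [filter_spec()].
#' @param train_fraction Training fraction for the stratified split.
#' @param variant t-test variant for screening.
#' @param alpha Screening significance threshold.
#' @param n_features Number of NIRS features selected.
#' @param with_clinical Fuse with age/BMI by PCA.
#' @param cost,gamma SVM hyperparameters.
#' @param cv_folds Cross-validation folds.
#' @param seed Global seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = "VV", sim = NULL, filter = filter_spec(),
                       train_fraction = 0.7, variant = "pooled", alpha = 0.05,
                       n_features = 2, with_clinical = FALSE, cost = 1,
                       gamma = NULL, cv_folds = 5, seed = 1L) {
  if (is.null(sim)) sim <- sim_config(mode, seed = derive_seed(seed, 1L))
  structure(
    list(mode = mode, sim = sim, filter = filter,
         train_fraction = train_fraction, variant = variant, alpha = alpha,
         n_features = n_features, with_clinical = with_clinical,
         cost = cost, gamma = gamma, cv_folds = cv_folds,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' Checks every type invariant the pipeline depends on and returns the list
#' of violations (empty when the config is valid); each issue names the
#' offending field and the rule.
#'
#' @param config A [run_config()].
#' @return Character vector of issues; `character(0)` if valid.
#' @export
validate_config <- function(config) {
  issues <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  chk(config$mode %in% c("VV", "VA"), "mode: must be VV or VA")
  chk(config$filter$cutoff_hz < config$sim$sampling_rate / 2,
      sprintf("filter$cutoff_hz: %g Hz is at or above Nyquist (%g Hz)",
              config$filter$cutoff_hz, config$sim$sampling_rate / 2))
  chk(config$filter$order >= 1, "filter$order: must be >= 1")
  chk(config$train_fraction > 0 && config$train_fraction < 1,
      "train_fraction: must lie in (0, 1)")
  chk(config$alpha >= 0 && config$alpha <= 1, "alpha: must lie in [0, 1]")
  chk(config$n_features >= 1, "n_features: must be >= 1")
  chk(config$cost > 0, "cost: must be positive")
  chk(is.null(config$gamma) || config$gamma > 0, "gamma: must be positive when set")
  chk(config$cv_folds >= 0, "cv_folds: must be non-negative")
  c(issues, validate_sim_config(config$sim))
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  ser <- list(
    mode = config$mode,
    sim = list(
      mode = config$sim$mode, sampling_rate = config$sim$sampling_rate,
      group_sizes = as.list(config$sim$group_sizes),
      plateaus = lapply(config$sim$plateaus, function(m) {
        list(HbO2 = unname(m[, "HbO2"]), HHb = unname(m[, "HHb"]))
      }),
      plateau_jitter_sd = config$sim$plateau_jitter_sd,
      transition_tau_s = config$sim$transition_tau_s,
      resp_band = config$sim$resp_band, card_band = config$sim$card_band,
      resp_amp = config$sim$resp_amp, card_amp = config$sim$card_amp,
      drift_slope_per_hr = config$sim$drift_slope_per_hr,
      white_noise_sd = config$sim$white_noise_sd,
      tsi_base_pct = config$sim$tsi_base_pct, tsi_gain = config$sim$tsi_gain,
      tsi_noise_sd = config$sim$tsi_noise_sd,
      apache_params = lapply(config$sim$apache_params, as.list),
      age_params = lapply(config$sim$age_params, as.list),
      bmi_params = lapply(config$sim$bmi_params, as.list),
      effect = config$sim$effect, seed = config$sim$seed
    ),
    filter = list(order = config$filter$order, cutoff_hz = config$filter$cutoff_hz),
    train_fraction = config$train_fraction, variant = config$variant,
    alpha = config$alpha, n_features = config$n_features,
    with_clinical = config$with_clinical, cost = config$cost,
    gamma = config$gamma, cv_folds = config$cv_folds, seed = config$seed
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  s <- yaml::read_yaml(path)
  mk <- function(p) {
    m <- cbind(HbO2 = as.numeric(p$HbO2), HHb = as.numeric(p$HHb))
    rownames(m) <- c("Baseline", paste0("Stage", 1:5))
    m
  }
  sim <- sim_config(
    mode = s$sim$mode, sampling_rate = s$sim$sampling_rate,
    group_sizes = c(n_low = s$sim$group_sizes$n_low,
                    n_high = s$sim$group_sizes$n_high),
    plateaus = lapply(s$sim$plateaus, mk),
    plateau_jitter_sd = s$sim$plateau_jitter_sd,
    transition_tau_s = s$sim$transition_tau_s,
    resp_band = as.numeric(s$sim$resp_band),
    card_band = as.numeric(s$sim$card_band),
    resp_amp = s$sim$resp_amp, card_amp = s$sim$card_amp,
    drift_slope_per_hr = s$sim$drift_slope_per_hr,
    white_noise_sd = s$sim$white_noise_sd,
    tsi_base_pct = s$sim$tsi_base_pct, tsi_gain = s$sim$tsi_gain,
    tsi_noise_sd = s$sim$tsi_noise_sd,
    apache_params = lapply(s$sim$apache_params, unlist),
    age_params = lapply(s$sim$age_params, unlist),
    bmi_params = lapply(s$sim$bmi_params, unlist),
    effect = s$sim$effect, seed = s$sim$seed
  )
  run_config(mode = s$mode, sim = sim,
             filter = filter_spec(s$filter$order, s$filter$cutoff_hz),
             train_fraction = s$train_fraction, variant = s$variant,
             alpha = s$alpha, n_features = s$n_features,
             with_clinical = s$with_clinical, cost = s$cost,
             gamma = s$gamma, cv_folds = s$cv_folds, seed = s$seed)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> extract features -> screen ->
#' classify, optionally writing every artifact (cohort CSVs, feature table,
#' screening table, model report JSON, human-readable summary) under
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for artifacts; `NULL` writes nothing.
#' @return The fitted [fit_severity()] object, with the config attached as
#'   `$config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid run config:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  cohort <- simulate_cohort(config$sim)
  table <- feature_table(cohort, spec = config$filter)
  fit <- fit_severity(
    table, with_clinical = config$with_clinical,
    split = split_spec(config$train_fraction, seed = derive_seed(config$seed, 2L)),
    variant = config$variant, n_features = config$n_features,
    cost = config$cost, gamma = config$gamma, cv_folds = config$cv_folds,
    cv_seed = derive_seed(config$seed, 3L)
  )
  fit$config <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    utils::write.csv(table, file.path(out_dir, "feature_table.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$screen, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    report <- list(
      mode = fit$mode, features = fit$features,
      with_clinical = fit$with_clinical,
      hyperparameters = fit$hyperparameters[c("cost", "gamma")],
      split = list(train = fit$split$train, test = fit$split$test,
                   counts = fit$split$counts),
      train_accuracy = fit$train$accuracy, test_accuracy = fit$test$accuracy,
      confusion = fit$test$confusion[c("tp", "fn", "fp", "tn", "accuracy",
                                       "sensitivity", "specificity")],
      cv = if (!is.null(fit$cv)) {
        list(fold_scores = fit$cv$fold_scores, mean = fit$cv$mean,
             sd = fit$cv$sd)
      },
      seed = config$seed
    )
    jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary_lines <- c(
      sprintf("ECMO NIRS severity pipeline (%s mode, seed %d)", config$mode,
              config$seed),
      sprintf("cohort: %d L / %d H subjects", sum(table$group == "L"),
              sum(table$group == "H")),
      sprintf("selected features: %s", paste(fit$features, collapse = ", ")),
      sprintf("train accuracy: %.1f%%", 100 * fit$train$accuracy),
      sprintf("test accuracy: %.1f%%", 100 * fit$test$accuracy),
      if (!is.null(fit$cv)) {
        sprintf("CV: mean %.1f%% +/- %.1f%%", 100 * fit$cv$mean, 100 * fit$cv$sd)
      }
    )
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }
  fit
}
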