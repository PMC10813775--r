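#' Default stage plateau matrices for a synthetic cohort
#'
#' Per-group, per-stage target plateau levels (arbitrary relative
#' concentration units) for the HbO2 and HHb channels, one row per protocol
#' stage (Baseline, Stage1..Stage5). The defaults encode the qualitative
#' group contrasts reported for each cannulation mode:
#' \itemize{
#'   \item VV: the high-severity group shows a larger Stage3-minus-Stage2
#'     HbO2 mean difference and a larger total-hemoglobin Stage2 mean;
#'   \item VA: the low-severity group shows a steeper HbO2 rise during
#'     Stage2, the high-severity group a larger HHb Stage5 mean.
#' }
#' With `effect = "null"` both groups share the low-group plateaus, giving a
#' cohort with no group signal (used for type-I-error calibration).
#'
#' @param mode `"VV"` or `"VA"`.
#' @param effect `"group"` for the mode-specific group contrasts, `"null"`
#'   for identical plateaus in both groups.
#' @return A list `list(L = , H = )`, each element a 6x2 matrix with columns
#'   `HbO2`, `HHb` and rows Baseline..Stage5.
#' @export
default_plateaus <- function(mode = c("VV", "VA"), effect = c("group", "null")) {
  mode <- match.arg(mode)
  effect <- match.arg(effect)
  mk <- function(hbo2, hhb) {
    m <- cbind(HbO2 = hbo2, HHb = hhb)
    rownames(m) <- c("Baseline", paste0("Stage", 1:5))
    m
  }
  if (mode == "VV") {
    L <- mk(c(0, -0.8, -0.1, 0.5, 0.9, 0.1), c(0, 0.4, 0.0, -0.2, -0.4, 0.0))
    H <- mk(c(0, -0.8, -0.1, 1.1, 0.9, 0.1), c(0, 0.4, 0.6, -0.2, -0.4, 0.0))
  } else {
    L <- mk(c(0, -1.0, 0.3, 0.6, 0.9, 0.1), c(0, 0.4, 0.1, -0.2, -0.4, 0.0))
    H <- mk(c(0, -0.5, 0.0, 0.4, 0.7, 0.1), c(0, 0.4, 0.1, -0.2, -0.4, 0.6))
  }
  if (effect == "null") H <- L
  list(L = L, H = H)
}

#' Simulation configuration for a synthetic ECMO cohort
#'
#' Collects every generative parameter of the synthetic-subject model:
#' stagewise plateau targets with first-order transitions, physiological
#' oscillations in the respiration (0.15-0.4 Hz) and cardiac (0.4-1.6 Hz)
#' bands, slow drift, white sensor noise, a TSI synthesis rule, and the
#' per-group clinical covariate distributions (APACHE II score, age, BMI).
#' The APACHE distributions respect the severity boundary by construction:
#' low-group scores are clipped to 0..24, high-group scores to 25..71.
#'
#' @param mode `"VV"` or `"VA"`.
#' @param sampling_rate Sampling rate in Hz (default 25, the instrument's
#'   processing rate). Must exceed twice the cardiac band upper edge.
#' @param group_sizes Named or positional pair `(n_low, n_high)`.
#' @param plateaus Per-group plateau matrices as from [default_plateaus()].
#' @param plateau_jitter_sd Between-subject SD of per-stage plateau
#'   perturbations (same units as the plateaus); the source of biological
#'   between-subject variability.
#' @param transition_tau_s First-order response time constant in seconds for
#'   stage transitions.
#' @param resp_band,card_band Frequency bands (Hz) from which each subject's
#'   respiration and cardiac oscillation frequencies are drawn.
#' @param resp_amp,card_amp Oscillation amplitudes (concentration units).
#' @param drift_slope_per_hr Linear drift slope per hour.
#' @param white_noise_sd White sensor noise SD on the Hb channels.
#' @param tsi_base_pct,tsi_gain,tsi_noise_sd TSI synthesis: TSI =
#'   base + gain * (HbO2 - HHb) + noise, in percent.
#' @param apache_params,age_params,bmi_params Per-group `list(L = c(mean, sd),
#'   H = c(mean, sd))` normal parameters for the clinical covariates.
#' @param effect `"group"` or `"null"`; with `"null"` the plateau and
#'   clinical distributions are identical across groups (labels stay valid).
#' @param seed Cohort RNG seed; per-subject seeds are derived from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mode = c("VV", "VA"),
                       sampling_rate = 25,
                       group_sizes = c(n_low = 14, n_high = 30),
                       plateaus = NULL,
                       plateau_jitter_sd = 0.08,
                       transition_tau_s = 30,
                       resp_band = c(0.15, 0.4),
                       card_band = c(0.4, 1.6),
                       resp_amp = 0.05,
                       card_amp = 0.03,
                       drift_slope_per_hr = 0.05,
                       white_noise_sd = 0.05,
                       tsi_base_pct = 65,
                       tsi_gain = 5,
                       tsi_noise_sd = 0.5,
                       apache_params = list(L = c(mean = 17, sd = 5),
                                            H = c(mean = 31, sd = 5)),
                       age_params = NULL,
                       bmi_params = NULL,
                       effect = c("group", "null"),
                       seed = 1L) {
  mode <- match.arg(mode)
  effect <- match.arg(effect)
  if (is.null(plateaus)) plateaus <- default_plateaus(mode, effect)
  if (is.null(age_params)) {
    age_params <- if (mode == "VA" && effect == "group") {
      # low-severity VA patients tend younger (age feeds the APACHE score)
      list(L = c(mean = 48, sd = 12), H = c(mean = 60, sd = 10))
    } else {
      list(L = c(mean = 55, sd = 12), H = c(mean = 55, sd = 12))
    }
  }
  if (is.null(bmi_params)) {
    bmi_params <- if (mode == "VV" && effect == "group") {
      # low-severity VV patients tend to carry higher BMI
      list(L = c(mean = 27.5, sd = 4), H = c(mean = 24.5, sd = 4))
    } else {
      list(L = c(mean = 26, sd = 4), H = c(mean = 26, sd = 4))
    }
  }
  cfg <- structure(
    list(mode = mode, sampling_rate = sampling_rate,
         group_sizes = c(n_low = unname(group_sizes[[1]]),
                         n_high = unname(group_sizes[[2]])),
         plateaus = plateaus, plateau_jitter_sd = plateau_jitter_sd,
         transition_tau_s = transition_tau_s,
         resp_band = resp_band, card_band = card_band,
         resp_amp = resp_amp, card_amp = card_amp,
         drift_slope_per_hr = drift_slope_per_hr,
         white_noise_sd = white_noise_sd,
         tsi_base_pct = tsi_base_pct, tsi_gain = tsi_gain,
         tsi_noise_sd = tsi_noise_sd,
         apache_params = apache_params, age_params = age_params,
         bmi_params = bmi_params, effect = effect,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  issues <- validate_sim_config(cfg)
  if (length(issues)) {
    stop("invalid simulation config:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg
}

# Returns a character vector of violated rules (empty if valid).
validate_sim_config <- function(cfg) {
  issues <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  chk(cfg$sampling_rate > 0, "sampling_rate: must be positive")
  chk(cfg$resp_band[1] > 0 && cfg$resp_band[2] <= cfg$card_band[1],
      "resp_band: must lie in (0, card_band lower edge]")
  chk(cfg$card_band[1] > cfg$resp_band[1] &&
        cfg$card_band[2] < cfg$sampling_rate / 2,
      "card_band: must lie above resp_band and below Nyquist")
  for (nm in c("plateau_jitter_sd", "resp_amp", "card_amp", "white_noise_sd",
               "tsi_noise_sd")) {
    chk(is.numeric(cfg[[nm]]) && cfg[[nm]] >= 0,
        paste0(nm, ": must be non-negative"))
  }
  chk(cfg$transition_tau_s > 0, "transition_tau_s: must be positive")
  chk(all(cfg$group_sizes >= 0), "group_sizes: must be non-negative")
  for (g in c("L", "H")) {
    chk(all(is.finite(cfg$apache_params[[g]])) && cfg$apache_params[[g]][["sd"]] >= 0,
        paste0("apache_params$", g, ": finite mean, non-negative sd"))
  }
  issues
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic ECMO cohort config: mode %s, %d L + %d H subjects, fs = %g Hz\n",
              x$mode, x$group_sizes[["n_low"]], x$group_sizes[["n_high"]],
              x$sampling_rate))
  cat(sprintf("  effect: %s | plateau jitter sd %g | tau %g s | seed %d\n",
              x$effect, x$plateau_jitter_sd, x$transition_tau_s, x$seed))
  cat(sprintf("  oscillations: resp %g in [%g, %g] Hz, cardiac %g in [%g, %g] Hz; noise sd %g\n",
              x$resp_amp, x$resp_band[1], x$resp_band[2],
              x$card_amp, x$card_band[1], x$card_band[2], x$white_noise_sd))
  invisible(x)
}

# Deterministic noise-free channel template: stagewise first-order relaxation
# toward each stage's plateau, continuous across stage boundaries, starting at
# the baseline plateau.
plateau_template <- function(plateaus, segments, tau_s, sampling_rate) {
  n <- segments$end_idx[nrow(segments)]
  out <- numeric(n)
  level <- plateaus[1L]
  for (k in seq_len(nrow(segments))) {
    idx <- (segments$start_idx[k] + 1L):segments$end_idx[k]
    t_rel <- (seq_along(idx) - 1L) / sampling_rate
    target <- plateaus[k]
    out[idx] <- target + (level - target) * exp(-t_rel / tau_s)
    level <- out[idx[length(idx)]]
  }
  out
}

#' Simulate one synthetic subject
#'
#' Generates a protocol-locked NIRS recording: each Hb channel follows
#' first-order transitions toward jittered group plateaus, plus linear drift,
#' one respiration-band sinusoid, one cardiac-band sinusoid (subject-specific
#' random frequency and phase) and white noise. TSI is synthesized as
#' `tsi_base_pct + tsi_gain * (HbO2 - HHb) + noise`. Clinical metadata
#' (APACHE II score, age, BMI) is drawn from the group's distributions; the
#' APACHE score never crosses the severity boundary (low <= 24 < high). The
#' result is fully determined by `(config, group, subject_seed)`.
#'
#' @param config A [sim_config()] object.
#' @param group `"L"` (low severity) or `"H"` (high severity).
#' @param subject_seed Integer seed for this subject's draws.
#' @param subject_id Subject identifier string.
#'
#' @return An object of class `nirs_recording`: list with `subject_id`,
#'   `mode`, `sampling_rate`, `channels` (named list `HbO2`, `HHb`, `TSI`),
#'   `n_samples`, `metadata` and `protocol`.
#' @export
simulate_subject <- function(config, group = c("L", "H"), subject_seed = 1L,
                             subject_id = "S001") {
  group <- match.arg(group)
  protocol <- ecmo_protocol(config$mode)
  fs <- config$sampling_rate
  n <- round(protocol_duration(protocol) * fs)
  segments <- segment_recording(n, fs, protocol)
  plateaus <- config$plateaus[[group]]

  with_seed(subject_seed, {
    jit <- matrix(stats::rnorm(length(plateaus), sd = config$plateau_jitter_sd),
                  nrow = nrow(plateaus))
    p <- plateaus + jit
    t_s <- (seq_len(n) - 1L) / fs
    f_resp <- stats::runif(1, config$resp_band[1], config$resp_band[2])
    f_card <- stats::runif(1, config$card_band[1], config$card_band[2])
    ph <- stats::runif(2, 0, 2 * pi)
    osc <- config$resp_amp * sin(2 * pi * f_resp * t_s + ph[1]) +
      config$card_amp * sin(2 * pi * f_card * t_s + ph[2])
    drift <- config$drift_slope_per_hr * t_s / 3600

    hbo2 <- plateau_template(p[, "HbO2"], segments, config$transition_tau_s, fs) +
      drift + osc + stats::rnorm(n, sd = config$white_noise_sd)
    hhb <- plateau_template(p[, "HHb"], segments, config$transition_tau_s, fs) -
      drift + osc * 0.5 + stats::rnorm(n, sd = config$white_noise_sd)
    tsi <- config$tsi_base_pct + config$tsi_gain * (hbo2 - hhb) +
      stats::rnorm(n, sd = config$tsi_noise_sd)

    ap <- config$apache_params[[group]]
    score <- round(stats::rnorm(1, ap[["mean"]], ap[["sd"]]))
    score <- if (group == "L") min(max(score, 0L), 24L) else min(max(score, 25L), 71L)
    agp <- config$age_params[[group]]
    bmp <- config$bmi_params[[group]]
    age <- min(max(stats::rnorm(1, agp[["mean"]], agp[["sd"]]), 18), 90)
    bmi <- min(max(stats::rnorm(1, bmp[["mean"]], bmp[["sd"]]), 14), 50)

    structure(
      list(subject_id = subject_id, mode = config$mode, sampling_rate = fs,
           channels = list(HbO2 = hbo2, HHb = hhb, TSI = tsi),
           n_samples = n,
           metadata = list(apache_score = as.integer(score),
                           age = age, bmi = bmi, group = group,
                           seed = as.integer(subject_seed)),
           protocol = protocol),
      class = "nirs_recording"
    )
  })
}

#' Noise-free channel templates for a subject's group
#'
#' Deterministic plateau-transition templates (no jitter, drift, oscillation
#' or noise) for the group's HbO2/HHb plateaus; used as reference signals in
#' spectral checks.
#'
#' @inheritParams simulate_subject
#' @return List of numeric vectors `HbO2`, `HHb`.
#' @export
subject_template <- function(config, group = c("L", "H")) {
  group <- match.arg(group)
  protocol <- ecmo_protocol(config$mode)
  fs <- config$sampling_rate
  n <- round(protocol_duration(protocol) * fs)
  segments <- segment_recording(n, fs, protocol)
  p <- config$plateaus[[group]]
  list(
    HbO2 = plateau_template(p[, "HbO2"], segments, config$transition_tau_s, fs),
    HHb = plateau_template(p[, "HHb"], segments, config$transition_tau_s, fs)
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("NIRS recording %s (%s mode): %d samples @ %g Hz, channels: %s\n",
              x$subject_id, x$mode, x$n_samples, x$sampling_rate,
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  group %s, APACHE II %d, age %.1f, BMI %.1f\n",
              x$metadata$group, x$metadata$apache_score,
              x$metadata$age, x$metadata$bmi))
  invisible(x)
}

#' Simulate a synthetic cohort
#'
#' Generates `n_low` low-severity and `n_high` high-severity subjects with
#' per-subject seeds derived deterministically from `config$seed`, so the
#' whole cohort is reproducible from the config alone.
#'
#' @param config A [sim_config()] object.
#' @return A list of [simulate_subject()] recordings (class `nirs_cohort`),
#'   low-severity subjects first.
#' @export
simulate_cohort <- function(config) {
  n_low <- config$group_sizes[["n_low"]]
  n_high <- config$group_sizes[["n_high"]]
  if (n_low + n_high < 2) stop("cohort must contain at least 2 subjects", call. = FALSE)
  if (n_low == 0 || n_high == 0) {
    warning("one group is empty; stratified splitting will fail downstream", call. = FALSE)
  }
  groups <- c(rep("L", n_low), rep("H", n_high))
  cohort <- lapply(seq_along(groups), function(i) {
    simulate_subject(config, groups[i], derive_seed(config$seed, i),
                     subject_id = sprintf("S%03d", i))
  })
  class(cohort) <- c("nirs_cohort", "list")
  cohort
}

#' Cohort metadata table
#'
#' @param cohort A list of recordings from [simulate_cohort()].
#' @return A data frame with one row per subject: `subject_id`, `mode`,
#'   `group`, `apache_score`, `age`, `bmi`, `seed`.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(subject_id = r$subject_id, mode = r$mode,
               group = r$metadata$group, apache_score = r$metadata$apache_score,
               age = r$metadata$age, bmi = r$metadata$bmi,
               seed = r$metadata$seed, stringsAsFactors = FALSE)
  }))
}

#' Write / read a recording as CSV
#'
#' The on-disk schema is one row per sample with columns `time_s` and one
#' column per channel (`HbO2`, `HHb`, `TSI`, plus `HbT` after preprocessing).
#'
#' @param recording A `nirs_recording`.
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `nirs_recording` (metadata must be supplied separately).
#' @export
write_recording <- function(recording, path) {
  df <- data.frame(time_s = (seq_len(recording$n_samples) - 1L) / recording$sampling_rate)
  for (ch in names(recording$channels)) df[[ch]] <- recording$channels[[ch]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param sampling_rate Sampling rate (Hz) of the stored series.
#' @param mode,metadata,subject_id Recording attributes not stored in the
#'   per-sample CSV.
#' @export
read_recording <- function(path, sampling_rate, mode = "VV",
                           metadata = list(), subject_id = basename(path)) {
  df <- utils::read.csv(path)
  channels <- as.list(df[setdiff(names(df), "time_s")])
  structure(
    list(subject_id = subject_id, mode = mode, sampling_rate = sampling_rate,
         channels = channels, n_samples = nrow(df), metadata = metadata,
         protocol = ecmo_protocol(mode)),
    class = "nirs_recording"
  )
}

#' Write a cohort to a directory
#'
#' One CSV per subject plus a `metadata.csv` index.
#'
#' @param cohort A `nirs_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in cohort) {
    write_recording(r, file.path(dir, paste0(r$subject_id, ".csv")))
  }
  utils::write.csv(cohort_metadata(cohort), file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
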