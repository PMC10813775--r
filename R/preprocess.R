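#' Low-pass filter specification
#'
#' The denoising filter applied to every channel: a fourth-order Butterworth
#' low-pass with 0.1 Hz cutoff, run forward and backward (zero-phase) so
#' stage timing is not shifted. The cutoff sits below the respiration band
#' (0.15-0.4 Hz), so both respiratory and cardiac oscillations are strongly
#' attenuated while the slow stage-locked hemodynamics pass.
#'
#' @param order Filter order (per pass).
#' @param cutoff_hz Cutoff frequency in Hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 0.1) {
  stopifnot_scalar_number(order, "order", positive = TRUE)
  stopifnot_scalar_number(cutoff_hz, "cutoff_hz", positive = TRUE)
  structure(list(kind = "butterworth_lowpass", order = as.integer(order),
                 cutoff_hz = cutoff_hz, application = "zero_phase"),
            class = "filter_spec")
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies the Butterworth design of `spec` forward and backward. Edge
#' transients are handled by odd-reflection padding of length
#' `3 * (order + 1)` at both ends before filtering; the padding is discarded
#' afterwards, so output length equals input length. Two passes square the
#' magnitude response, giving
#' \deqn{|H_{2}(f)| = 1 / (1 + (f/f_c)^{2\,order})}
#' and exactly zero phase.
#'
#' @param x Numeric series.
#' @param sampling_rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return The filtered series, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, sampling_rate, spec = filter_spec()) {
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (spec$cutoff_hz >= sampling_rate / 2) {
    stop(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)",
                 spec$cutoff_hz, sampling_rate / 2), call. = FALSE)
  }
  pad <- 3L * (spec$order + 1L)
  if (length(x) <= pad) {
    stop(sprintf("series too short to filter: %d samples, need > %d",
                 length(x), pad), call. = FALSE)
  }
  bf <- signal::butter(spec$order, 2 * spec$cutoff_hz / sampling_rate, type = "low")
  n <- length(x)
  # odd (point-symmetric) reflection about the first and last samples, plus
  # steady-state initial conditions at the first padded value, so slow filters
  # start settled rather than relaxing from zero
  pre <- 2 * x[1L] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(pre, x, post)
  run <- function(z) {
    v <- z[1L]
    signal::filter(bf$b, bf$a, z,
                   init.x = rep(v, spec$order), init.y = rep(v, spec$order))
  }
  y <- rev(run(rev(run(xp))))
  y[(pad + 1L):(pad + n)]
}

#' Squared-magnitude response of the two-pass Butterworth filter
#'
#' Closed-form amplitude gain of [lowpass_zero_phase()] at frequency `f`:
#' a single Butterworth pass has `|H(f)|^2 = 1 / (1 + (f/fc)^(2 order))`, and
#' forward-backward filtering applies it twice.
#'
#' @param f Frequency in Hz.
#' @param spec A [filter_spec()].
#' @return Amplitude gain (not power) of the zero-phase filter at `f`.
#' @export
butter_two_pass_gain <- function(f, spec = filter_spec()) {
  1 / (1 + (f / spec$cutoff_hz)^(2 * spec$order))
}

#' Min-max normalization to [0, 1]
#'
#' Rescales a series to the unit interval, `(x - min) / (max - min)`,
#' preserving proportions; applied per channel over the full recording. A
#' constant series is degenerate: it is mapped to all zeros with a warning.
#'
#' @param x Numeric series.
#' @return A series in `[0, 1]` with attributes `min` and `max` holding the
#'   original bounds (enabling exact de-normalization).
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L) stop("cannot normalize an empty series", call. = FALSE)
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    warning("constant series: min-max normalization degenerate, returning zeros",
            call. = FALSE)
    out <- rep(0, length(x))
  } else {
    out <- (x - lo) / (hi - lo)
  }
  attr(out, "min") <- lo
  attr(out, "max") <- hi
  out
}

#' Total hemoglobin from the oxy/deoxy channels
#'
#' `HbT = HbO2 + HHb`, computed elementwise on the filtered,
#' pre-normalization signals (summation and linear filtering commute, but
#' min-max rescaling does not, so HbT must be formed before normalization).
#'
#' @param hbo2,hhb Equal-length series.
#' @return Their elementwise sum.
#' @export
derive_hbt <- function(hbo2, hhb) {
  if (length(hbo2) != length(hhb)) {
    stop("HbO2 and HHb series must have equal length", call. = FALSE)
  }
  hbo2 + hhb
}

#' Preprocess a recording
#'
#' Runs the full conditioning chain on a raw recording: each of HbO2, HHb
#' and TSI is low-pass filtered (zero phase), HbT is derived from the
#' filtered Hb channels, and all four channels are min-max normalized
#' independently. Normalization bounds and the filter spec are stored under
#' `$preprocessing` so the transform is auditable and invertible.
#'
#' @param recording A `nirs_recording` with channels `HbO2`, `HHb`, `TSI`.
#' @param spec A [filter_spec()].
#' @param normalize_tsi Normalize the TSI channel too (default TRUE; set
#'   FALSE to keep TSI in percent).
#' @return The recording with channels `HbO2`, `HHb`, `HbT`, `TSI`
#'   (filtered, normalized) and a `preprocessing` provenance entry.
#' @export
preprocess_recording <- function(recording, spec = filter_spec(),
                                 normalize_tsi = TRUE) {
  need <- c("HbO2", "HHb", "TSI")
  missing_ch <- setdiff(need, names(recording$channels))
  if (length(missing_ch)) {
    stop("recording is missing channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  fs <- recording$sampling_rate
  filt <- lapply(recording$channels[need], lowpass_zero_phase,
                 sampling_rate = fs, spec = spec)
  filt$HbT <- derive_hbt(filt$HbO2, filt$HHb)
  order_out <- c("HbO2", "HHb", "HbT", "TSI")
  bounds <- list()
  out <- list()
  for (ch in order_out) {
    if (ch == "TSI" && !normalize_tsi) {
      out[[ch]] <- filt[[ch]]
      next
    }
    norm <- minmax_normalize(filt[[ch]])
    bounds[[ch]] <- c(min = attr(norm, "min"), max = attr(norm, "max"))
    attributes(norm) <- NULL
    out[[ch]] <- norm
  }
  recording$channels <- out
  recording$preprocessing <- list(filter = spec, normalization_bounds = bounds,
                                  normalize_tsi = normalize_tsi)
  recording
}
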