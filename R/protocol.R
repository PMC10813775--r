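#' ECMO pump-speed measurement protocol
#'
#' Builds the canonical six-stage pump-speed protocol used for lower-limb
#' NIRS monitoring of ECMO patients. The recording opens with a 15-minute
#' baseline at the clinical pump speed, then the speed is stepped by one
#' "unit" per stage: down one unit, back to baseline, up one, up two, and
#' finally reset to the initial speed for a closing 15-minute block. One
#' speed unit is 300 rpm for veno-venous (VV) and 500 rpm for veno-arterial
#' (VA) cannulation, so the same relative perturbation is applied to both
#' modes. Total duration is 4200 s (70 min).
#'
#' @param mode ECMO cannulation mode, `"VV"` or `"VA"`.
#'
#' @return An object of class `ecmo_protocol`: a list with `mode`, `unit_rpm`
#'   and a data frame `stages` with columns `label`, `duration_s` and
#'   `speed_delta_units` (speed offset from the initial speed, in units).
#'
#' @examples
#' p <- ecmo_protocol("VV")
#' p$unit_rpm            # 300
#' sum(p$stages$duration_s)  # 4200
#' @export
ecmo_protocol <- function(mode = c("VV", "VA")) {
  if (length(mode) != 1L && !identical(mode, c("VV", "VA"))) {
    mode <- mode[1L]
  }
  mode <- match.arg(toupper(mode), c("VV", "VA"))
  stages <- data.frame(
    label = c("Baseline", paste0("Stage", 1:5)),
    duration_s = c(900, 600, 600, 600, 600, 900),
    speed_delta_units = c(0L, -1L, 0L, 1L, 2L, 0L),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      mode = mode,
      unit_rpm = if (mode == "VV") 300L else 500L,
      stages = stages
    ),
    class = "ecmo_protocol"
  )
}

#' @export
print.ecmo_protocol <- function(x, ...) {
  cat(sprintf("ECMO pump-speed protocol (%s mode, 1 unit = %d rpm)\n",
              x$mode, x$unit_rpm))
  df <- x$stages
  df$speed_delta_rpm <- df$speed_delta_units * x$unit_rpm
  print(df, row.names = FALSE)
  cat(sprintf("Total duration: %d s (%.0f min)\n",
              sum(df$duration_s), sum(df$duration_s) / 60))
  invisible(x)
}

#' Total protocol duration in seconds
#' @param protocol An [ecmo_protocol()] object.
#' @return Duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  sum(protocol$stages$duration_s)
}

#' Segment a recording into protocol stages
#'
#' Maps the protocol timeline onto sample indices. Segments are 1-based,
#' inclusive-start / exclusive-end in the `start`/`end` columns expressed as
#' 0-based half-open intervals `[start_idx, end_idx)`, contiguous and jointly
#' covering `[0, round(4200 * sampling_rate))`. Sample counts per stage use
#' round-half-to-even on `duration_s * sampling_rate`.
#'
#' @param n_samples Number of samples in the recording.
#' @param sampling_rate Sampling rate in Hz.
#' @param protocol An [ecmo_protocol()] object (or any object with the same
#'   `stages` layout, e.g. a config override).
#'
#' @return A data frame with one row per stage: `label`, `start_idx`
#'   (0-based, inclusive), `end_idx` (exclusive), `speed_delta_units`.
#'   Trailing samples beyond the protocol duration are excluded with a
#'   warning; a recording shorter than the protocol is an error reporting
#'   the deficit.
#'
#' @examples
#' segs <- segment_recording(105000, 25, ecmo_protocol("VV"))
#' segs[1, c("start_idx", "end_idx")]  # Baseline = [0, 22500)
#' @export
segment_recording <- function(n_samples, sampling_rate, protocol = ecmo_protocol("VV")) {
  stopifnot_scalar_number(n_samples, "n_samples", positive = TRUE)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  durations <- protocol$stages$duration_s
  lengths <- round(durations * sampling_rate)
  total <- sum(lengths)
  if (n_samples < total) {
    stop(sprintf(
      "recording too short for protocol: %d samples provided, %d required (deficit %d)",
      n_samples, total, total - n_samples
    ), call. = FALSE)
  }
  if (n_samples > total) {
    warning(sprintf(
      "recording has %d samples beyond the %d-sample protocol; trailing samples excluded",
      n_samples - total, total
    ), call. = FALSE)
  }
  end_idx <- cumsum(lengths)
  start_idx <- c(0, end_idx[-length(end_idx)])
  data.frame(
    label = protocol$stages$label,
    start_idx = as.integer(start_idx),
    end_idx = as.integer(end_idx),
    speed_delta_units = protocol$stages$speed_delta_units,
    stringsAsFactors = FALSE
  )
}

# Extract the samples of one segment (row of segment_recording output) from a
# channel vector. Segments are 0-based half-open, R vectors 1-based.
segment_slice <- function(x, segment) {
  x[(segment$start_idx + 1L):segment$end_idx]
}
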