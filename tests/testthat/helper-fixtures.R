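# Shared fixtures. Simulations in the tests run at reduced sampling rates
# (4-5 Hz instead of the instrument's 25 Hz); the protocol timeline, noise
# bands and effect sizes are unchanged, only the sample density drops.

# A raw recording built directly from channel vectors (protocol attached),
# for feature-extraction oracles that bypass the simulator.
make_recording <- function(channels, sampling_rate = 1, mode = "VV",
                           metadata = list(apache_score = 10L, age = 50,
                                           bmi = 25, group = "L")) {
  n <- length(channels[[1]])
  structure(
    list(subject_id = "T001", mode = mode, sampling_rate = sampling_rate,
         channels = channels, n_samples = n, metadata = metadata,
         protocol = ecmo_protocol(mode)),
    class = "nirs_recording"
  )
}

# Stagewise step channel at fs = 1 Hz: value `levels[k]` throughout stage k.
step_channel <- function(levels, fs = 1) {
  segs <- segment_recording(round(4200 * fs), fs, ecmo_protocol("VV"))
  unlist(lapply(seq_len(nrow(segs)), function(k) {
    rep(levels[k], segs$end_idx[k] - segs$start_idx[k])
  }))
}

# Small fast cohort configs.
small_cfg <- function(mode = "VV", effect = "group", n_low = 6, n_high = 6,
                      seed = 1L, fs = 4, ...) {
  sim_config(mode, sampling_rate = fs, group_sizes = c(n_low, n_high),
             effect = effect, seed = seed, ...)
}
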