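test_that("MBLL conversion inverts the forward optical-density model", {
  p <- mbll_params()
  t <- seq(0, 10, by = 0.01)
  hbo2 <- 0.02 * sin(t)
  hhb <- 0.01 * cos(t)
  od <- make_optical_densities(hbo2, hhb, p)
  back <- mbll_convert(od, p)
  expect_lt(max(abs(back$HbO2 - hbo2)), 1e-9)
  expect_lt(max(abs(back$HHb - hhb)), 1e-9)

  # zero concentrations give zero OD at both wavelengths
  od0 <- make_optical_densities(rep(0, 5), rep(0, 5), p)
  expect_equal(unname(od0), matrix(0, 5, 2))

  # identity system: epsilon = I, d * DPF = 1 => concentrations equal ODs
  ident <- mbll_params(extinction = diag(2), distance_cm = 1, dpf = c(1, 1))
  out <- mbll_convert(cbind(hbo2, hhb), ident)
  expect_equal(out$HbO2, hbo2)
  expect_equal(out$HHb, hhb)
})

test_that("forward OD model matches a hand-computed matrix product", {
  eps <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("HbO2", "HHb")))
  p <- mbll_params(extinction = eps, distance_cm = 3, dpf = c(4, 4))
  od <- make_optical_densities(0.5, 0.25, p)
  # lambda1: (1 * 0.5 + 2 * 0.25) * 3 * 4 = 12; lambda2: (3 * 0.5 + 4 * 0.25) * 12 = 30
  expect_equal(unname(od[1, ]), c(12, 30))
})

test_that("singular extinction matrices and length mismatches are rejected", {
  expect_error(mbll_params(extinction = matrix(c(1, 2, 2, 4), 2)), "singular")
  expect_error(mbll_convert(list(1:5, 1:4)), "equal length")
})

test_that("zero-phase filter passes DC and attenuates tones per the closed-form magnitude", {
  fs <- 25
  t <- seq(0, 400, by = 1 / fs)
  expect_lt(max(abs(lowpass_zero_phase(rep(3, length(t)), fs) - 3)), 1e-6)

  # 1 Hz tone: steady-state amplitude ratio ~ 1 / (1 + (1 / 0.1)^8) = 1e-8
  y <- lowpass_zero_phase(sin(2 * pi * 1 * t), fs)
  amp <- max(abs(y[2000:8000]))
  expect_lt(amp, 2 * butter_two_pass_gain(1))
  expect_gt(amp, 0.5 * butter_two_pass_gain(1))

  # respiration band edge (0.15 Hz): measured amplitude matches the oracle,
  # and is below 10% of the input amplitude
  y15 <- lowpass_zero_phase(sin(2 * pi * 0.15 * t), fs)
  amp15 <- max(abs(y15[2000:8000]))
  expect_equal(amp15, butter_two_pass_gain(0.15), tolerance = 0.01)
  expect_lt(amp15, 0.1)
})

test_that("filtering is zero-phase: passband sinusoid peaks at lag 0", {
  fs <- 25
  t <- seq(0, 1000, by = 1 / fs)
  x <- sin(2 * pi * 0.01 * t)
  y <- lowpass_zero_phase(x, fs)
  mid <- 5000:20000
  lags <- -10:10
  cc <- vapply(lags, function(l) stats::cor(x[mid], y[mid + l]), numeric(1))
  expect_equal(lags[which.max(cc)], 0L)
})

test_that("filter is linear and near-idempotent in the deep passband", {
  fs <- 25
  set.seed(31)
  a <- rnorm(3000); b <- rnorm(3000)
  expect_lt(max(abs(lowpass_zero_phase(a, fs) + lowpass_zero_phase(b, fs) -
                      lowpass_zero_phase(a + b, fs))), 1e-8)
  t <- seq(0, 2000, by = 1 / fs)
  x <- sin(2 * pi * 0.01 * t)
  y1 <- lowpass_zero_phase(x, fs)
  y2 <- lowpass_zero_phase(y1, fs)
  mid <- 10000:40000
  expect_lt(max(abs(y2[mid] - y1[mid])) / max(abs(y1[mid])), 0.01)
})

test_that("filter rejects unusable inputs", {
  expect_error(lowpass_zero_phase(rnorm(100), 0.1), "Nyquist")
  expect_error(lowpass_zero_phase(rnorm(10), 25), "too short")
})

test_that("min-max normalization maps to [0,1] and is affine-invariant", {
  expect_equal(as.numeric(minmax_normalize(c(2, 4, 6))), c(0, 0.5, 1))
  set.seed(8)
  x <- rnorm(500)
  for (ab in list(c(2, 0), c(0.5, -3), c(10, 100))) {
    expect_equal(as.numeric(minmax_normalize(ab[1] * x + ab[2])),
                 as.numeric(minmax_normalize(x)), tolerance = 1e-12)
  }
  n <- minmax_normalize(x)
  expect_true(all(n >= 0 & n <= 1))
  # stored bounds de-normalize exactly
  expect_equal(as.numeric(n) * (attr(n, "max") - attr(n, "min")) + attr(n, "min"),
               x, tolerance = 1e-12)
})

test_that("constant series normalize to zeros with a warning", {
  expect_warning(out <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(as.numeric(out), c(0, 0, 0))
})

test_that("HbT is the elementwise channel sum and commutes with filtering", {
  expect_equal(derive_hbt(0.3, 0.1), 0.4)
  x <- rnorm(100)
  expect_equal(derive_hbt(x, -x), rep(0, 100))
  expect_error(derive_hbt(1:3, 1:4), "equal length")
  a <- rnorm(2000); b <- rnorm(2000)
  expect_lt(max(abs(derive_hbt(lowpass_zero_phase(a, 25), lowpass_zero_phase(b, 25)) -
                      lowpass_zero_phase(derive_hbt(a, b), 25))), 1e-8)
})

test_that("preprocessing yields four normalized channels with stored provenance", {
  cfg <- small_cfg(seed = 3L)
  rec <- simulate_subject(cfg, "H", 21L)
  pp <- preprocess_recording(rec)
  expect_named(pp$channels, c("HbO2", "HHb", "HbT", "TSI"))
  for (ch in pp$channels) {
    expect_true(all(ch >= 0 & ch <= 1))
    expect_equal(length(ch), rec$n_samples)
  }
  expect_named(pp$preprocessing$normalization_bounds,
               c("HbO2", "HHb", "HbT", "TSI"))
  # de-normalization round-trip for one channel
  b <- pp$preprocessing$normalization_bounds$HbO2
  raw_filt <- lowpass_zero_phase(rec$channels$HbO2, cfg$sampling_rate)
  expect_equal(pp$channels$HbO2 * (b[["max"]] - b[["min"]]) + b[["min"]],
               raw_filt, tolerance = 1e-10)
  expect_error(preprocess_recording(make_recording(list(HbO2 = 1:10))), "HHb")
})

test_that("normalization preserves the ordering of stage plateaus", {
  cfg <- small_cfg(fs = 4, plateau_jitter_sd = 0, resp_amp = 0, card_amp = 0,
                   drift_slope_per_hr = 0, white_noise_sd = 0, tsi_noise_sd = 0)
  rec <- simulate_subject(cfg, "L", 1L)
  pp <- preprocess_recording(rec)
  segs <- segment_recording(rec$n_samples, 4)
  m_norm <- stage_mean(pp$channels$HbO2, segs)
  m_raw <- stage_mean(rec$channels$HbO2, segs)
  expect_equal(order(m_norm), order(m_raw))
})
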