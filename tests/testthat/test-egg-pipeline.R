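# EGG preprocessing chain: anti-alias downsampling, Welch spectra, peak
# selection, narrow zero-phase bandpass, decimation to the BOLD rate.

test_that("anti-alias downsampling preserves the gastric band and kills >5 Hz content", {
  tt <- (0:(900 * 200 - 1)) / 200
  tone <- cos(2 * pi * 0.05 * tt)
  hum <- cos(2 * pi * 6 * tt)
  raw <- egg_recording(cbind(tone, hum), rate = 200)
  ds <- lowpass_downsample(raw)
  expect_equal(ds$rate, 10)
  expect_equal(nrow(ds$samples), 9000L)
  # deep-passband tone: amplitude preserved within 1% (interior samples)
  mid <- 2000:7000
  expect_lt(abs(max(abs(ds$samples[mid, 1])) - 1), 0.01)
  # 6 Hz tone: residual power at most 1% of input power
  expect_lt(mean(ds$samples[mid, 2]^2) / mean(hum^2), 0.01)
  # identity when already at the target rate
  at10 <- egg_recording(matrix(rnorm(100), ncol = 1), rate = 10)
  expect_identical(lowpass_downsample(at10), at10)
  expect_error(lowpass_downsample(egg_recording(rnorm(100), rate = 15)),
               "twice the target")
})

test_that("Welch estimate has the documented segmentation, peak, and Parseval scaling", {
  tt <- (0:8999) / 10
  est <- welch_psd(cos(2 * pi * 0.05 * tt), rate = 10)
  expect_equal(est$n_segments, 15L)          # (900-200)/50 + 1
  expect_equal(diff(est$frequencies[1:2]), 0.005)
  expect_equal(est$frequencies[which.max(est$power[, 1])], 0.05)

  set.seed(1)
  x <- rnorm(9000)
  est2 <- welch_psd(x, rate = 10)
  integral <- sum(est2$power[, 1]) * 0.005
  expect_lt(abs(integral / var(x) - 1), 0.1)

  expect_error(welch_psd(rnorm(100), rate = 10), "shorter than one window")
})

test_that("peak selection is scale-invariant across channels and flags weak signals", {
  set.seed(2)
  tt <- (0:8999) / 10
  sig <- cos(2 * pi * 0.048 * tt) + rnorm(9000, 0, 0.3)
  est <- welch_psd(cbind(2 * sig, sig), rate = 10)
  pk <- select_gastric_peak(est)
  expect_equal(pk$channel, 1L)
  pk2 <- select_gastric_peak(welch_psd(cbind(sig, 2 * sig), rate = 10))
  expect_equal(pk2$channel, 2L)
  expect_equal(pk$peak_frequency, pk2$peak_frequency)
  expect_equal(pk$quality, "ok")

  noise <- welch_psd(matrix(rnorm(9000 * 2), ncol = 2), rate = 10)
  expect_equal(select_gastric_peak(noise)$quality, "weak")
  expect_error(select_gastric_peak(est, band = c(6, 7)), "band")
})

test_that("the gastric bandpass design meets its gain and symmetry contract", {
  spec <- design_gastric_bandpass(0.05, rate = 10)
  expect_length(spec$taps, 1001L)            # round(5 * 10 / 0.05) + 1
  expect_equal(spec$taps, rev(spec$taps), tolerance = 1e-12)
  H <- function(f, taps, fs) Mod(sum(taps * exp(-2i * pi * f * (seq_along(taps) - 1) / fs)))
  g_center <- H(0.05, spec$taps, 10)
  expect_gte(g_center, 0.9)
  expect_lte(g_center, 1.1)
  # single-pass response squared (forward-backward) at +/- 0.03 Hz offsets
  expect_lte(H(0.08, spec$taps, 10)^2 / g_center^2, 0.25)
  expect_lte(H(0.02, spec$taps, 10)^2 / g_center^2, 0.25)

  spec_bold <- design_gastric_bandpass(0.05, rate = 0.5)
  expect_equal(length(spec_bold$taps), 51L)   # round(5 * 0.5 / 0.05) + 1
  g_bold <- H(0.05, spec_bold$taps, 0.5)
  expect_gte(g_bold, 0.9)
  expect_lte(g_bold, 1.1)

  expect_error(design_gastric_bandpass(0.01, rate = 10), "lower edge")
  expect_error(design_gastric_bandpass(0.24, rate = 0.5), "Nyquist")
})

test_that("forward-backward filtering is zero-phase and suppresses DC", {
  spec <- design_gastric_bandpass(0.05, rate = 10)
  tt <- (0:8999) / 10
  x <- cos(2 * pi * 0.05 * tt)
  y <- zero_phase_bandpass(x, spec)
  mid <- 3001:6000
  # cross-correlation against the input peaks at zero lag
  lags <- -5:5
  cc <- vapply(lags, function(L) cor(x[mid], y[mid + L]), 0)
  expect_equal(lags[which.max(cc)], 0L)
  # interior phase error below 0.01 radian
  ph_in <- instantaneous_phase(x)[mid]
  ph_out <- instantaneous_phase(y)[mid]
  expect_lt(max(abs(wrap_phase(ph_out - ph_in))), 0.01)

  expect_lt(max(abs(zero_phase_bandpass(rep(1, 9000), spec)[mid])), 1e-6)
  expect_error(zero_phase_bandpass(rnorm(2000), spec), "3 filter lengths")
})

test_that("decimation to the BOLD rate keeps values at shared time points", {
  tt <- (0:8999) / 10
  x <- cos(2 * pi * 0.05 * tt)
  y <- resample_to_bold(x, rate = 10)
  expect_length(y, 450L)
  expect_equal(attr(y, "rate"), 0.5)
  expect_equal(as.numeric(y), x[seq(1, 9000, by = 20)])
})

test_that("the full extraction chain recovers a synthetic rhythm end to end", {
  set.seed(9)
  ph <- simulate_gastric_phase(900, 10, 0.048, drift_sd = 5e-5)
  egg <- synthesize_egg_run(ph, channel_gains = c(0.5, 1, 0.75))
  g <- extract_gastric_signal(egg)
  expect_s3_class(g, "gastric_signal")
  expect_equal(g$quality, "ok")
  expect_length(g$values, 450L)
  expect_lt(abs(g$peak_frequency - 0.048), 0.005 + 1e-9)
  expect_lt(abs(mean(g$values)), 1e-8)

  # deterministic: same input, same output
  expect_identical(extract_gastric_signal(egg), g)

  # positive rescaling of the raw data changes nothing but the scale
  egg_scaled <- egg
  egg_scaled$samples <- egg$samples * 3.7
  g2 <- extract_gastric_signal(egg_scaled)
  expect_equal(g2$peak_frequency, g$peak_frequency)
  expect_equal(g2$source_channel, g$source_channel)
  expect_equal(g2$values / sd(g2$values), g$values / sd(g$values),
               tolerance = 1e-9)

  # noise-only recording comes back flagged weak
  set.seed(10)
  noisy <- egg_recording(matrix(rnorm(9000 * 3), ncol = 3), rate = 10)
  expect_equal(extract_gastric_signal(noisy)$quality, "weak")
})

test_that("peak recovery stays within one Welch bin across the band", {
  set.seed(123)
  f0s <- runif(100, 0.038, 0.060)
  hits <- vapply(f0s, function(f0) {
    ph <- simulate_gastric_phase(900, 10, f0, drift_sd = 5e-5)
    egg <- synthesize_egg_run(ph, channel_gains = 1,
                              contaminant_spec = list(broadband_sd = 0.5))
    g <- extract_gastric_signal(egg)
    f_true <- mean(attr(ph, "frequency"))
    abs(g$peak_frequency - f_true) <= 0.005 + 1e-9
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
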