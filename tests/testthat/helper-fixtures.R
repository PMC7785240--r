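# Shared fixtures, all built in code.

# Manifest with S sessions of r runs each, dates two days apart.
toy_manifest <- function(n_sessions, runs_per_session) {
  dates <- as.Date("2019-07-01") + 2L * (seq_len(n_sessions) - 1L)
  grid <- expand.grid(run = seq_len(runs_per_session),
                      session = seq_len(n_sessions))
  data.frame(
    run_id = sprintf("S%02dR%d", grid$session, grid$run),
    session = grid$session,
    session_date = dates[grid$session],
    included = TRUE,
    exclusion_reason = "",
    stringsAsFactors = FALSE)
}

# A clean gastric_signal built directly from a tone (no pipeline).
tone_gastric <- function(f0 = 0.05, n = 450, rate = 0.5,
                         run_id = "R1", date = as.Date("2019-07-01"),
                         phase0 = 0) {
  tt <- (seq_len(n) - 1L) / rate
  v <- cos(2 * pi * f0 * tt + phase0)
  structure(
    list(values = v - mean(v), rate = rate, peak_frequency = f0,
         source_channel = 1L, band = c(f0 - 0.015, f0 + 0.015),
         quality = "ok", run_id = run_id, session_date = date),
    class = "gastric_signal")
}

# Small fast study configuration: EGG generated directly at the 10 Hz
# pipeline rate (identical gastric-band content, no initial decimation).
fast_config <- function(n_sessions = 4, runs_per_session = 2, seed = 1, ...) {
  sim_config(n_sessions = n_sessions, runs_per_session = runs_per_session,
             egg_rate = 10, seed = seed, ...)
}

# Fraction of a series' variance lying within a frequency band (test-side
# periodogram, independent of package internals).
band_fraction <- function(x, rate, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1L) * rate / n
  f <- pmin(f, rate - f)
  sum(p[f >= lo & f <= hi]) / sum(p[-1L])
}
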