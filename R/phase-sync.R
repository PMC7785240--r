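# Instantaneous phases, the phase-locking value, and the phase-adjusted
# variance-explained measure (P.V.A.F.).

#' Bandpass-filter an RSN time course with a run's gastric filter parameters
#'
#' Each network time course is filtered with the same centre frequency and
#' half-width as the EGG of the corresponding run, with the FIR redesigned
#' for the BOLD sampling rate (about 51 taps at 0.5 Hz for a 0.05 Hz centre).
#'
#' @param x numeric RSN time course at the BOLD rate.
#' @param spec a `bandpass_spec` whose `rate` matches the series.
#' @return zero-phase narrowband series, same length.
#' @export
bandpass_rsn <- function(x, spec) {
  stopifnot(inherits(spec, "bandpass_spec"))
  zero_phase_bandpass(x, spec)
}

#' Build the BOLD-rate bandpass specification for a run
#'
#' @param gastric a `gastric_signal` (supplies the run's peak frequency).
#' @param half_width,order_cycles filter parameters (defaults 0.015 Hz, 5).
#' @param bold_rate BOLD sampling rate in Hz.
#' @return a `bandpass_spec` at `bold_rate`.
#' @export
rsn_bandpass_spec <- function(gastric, half_width = 0.015, order_cycles = 5,
                              bold_rate = 0.5) {
  stopifnot(inherits(gastric, "gastric_signal"))
  design_gastric_bandpass(gastric$peak_frequency, half_width, order_cycles,
                          bold_rate)
}

#' Discard edge samples from both ends of a series
#'
#' Removes the first and last `n_per_end` samples (default 15 volumes, i.e.
#' 30 s at the BOLD rate) to avoid filter and Hilbert-transform edge
#' effects; a 450-sample run becomes a 420-sample (840 s) analysis window.
#'
#' @param x numeric vector.
#' @param n_per_end samples to drop at each end (default 15).
#' @return trimmed vector.
#' @export
trim_edges <- function(x, n_per_end = 15) {
  if (n_per_end == 0L) return(x)
  if (length(x) <= 2L * n_per_end) {
    stop("trim_edges: series not longer than the trimmed portion")
  }
  x[(n_per_end + 1L):(length(x) - n_per_end)]
}

#' Instantaneous phase of a narrowband series
#'
#' Argument of the analytic signal (FFT-based Hilbert transform), wrapped to
#' (-pi, pi]. Phase is invariant to positive amplitude scaling.
#'
#' @param x zero-mean narrowband numeric series.
#' @return numeric vector of phases in (-pi, pi].
#' @export
instantaneous_phase <- function(x) {
  if (all(x == 0)) stop("instantaneous_phase: all-zero series has no phase")
  wrap_phase(Arg(analytic_signal(x - mean(x))))
}

#' Phase-locking value between two phase series
#'
#' The modulus of the time-averaged complex phase difference,
#' `|mean(exp(i * (phi_x - phi_y)))|`. Ranges from 0 (no synchrony) to 1
#' (perfect synchrony); invariant to constant phase offsets (temporal
#' delays) and to signal amplitudes.
#'
#' @param phase_x,phase_y numeric phase vectors of equal length (radians).
#' @return scalar in `[0, 1]`.
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    stop("plv: phase series differ in length; refusing to truncate")
  }
  if (length(phase_x) < 2L) stop("plv: need at least 2 samples")
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Von Mises location estimate of a phase-difference series
#'
#' Maximum-likelihood estimate of the location parameter mu of a von Mises
#' model for the instantaneous phase difference; equal to the circular mean
#' (the argument of the mean resultant vector). The concentration kappa is
#' deliberately not estimated, as only the location is used downstream.
#'
#' @param delta_psi numeric vector of phase differences in radians.
#' @return `mu_hat` in (-pi, pi].
#' @export
estimate_phase_offset <- function(delta_psi) {
  if (length(delta_psi) < 2L) stop("estimate_phase_offset: need at least 2 samples")
  r <- mean(exp(1i * delta_psi))
  if (Mod(r) < 1e-12) {
    stop("estimate_phase_offset: zero resultant; offset undefined")
  }
  mu <- Arg(r)
  if (mu <= -pi) mu <- pi
  mu
}

#' Phase-adjusted percent variance accounted for (P.V.A.F.)
#'
#' Estimates how much of a narrowband network signal is explained by the
#' gastric signal after compensating the overall phase lag between them.
#' The instantaneous phase difference `delta_psi = psi(EGG) - psi(RSN)` is
#' modelled as von Mises; its location MLE `mu_hat` is used to rotate the
#' analytic network signal, and the squared Pearson correlation between the
#' gastric series and the real part of the rotated signal is reported as
#' R-squared. (The squared correlation is identical whichever series is
#' treated as the regressor.)
#'
#' @param gastric narrowband gastric series (BOLD rate).
#' @param rsn narrowband network series, same length and rate.
#' @param n_trim edge samples to drop per end after the analytic transform
#'   (default 15; set 0 for pre-trimmed inputs).
#' @return list with `mu_hat` (radians, in (-pi, pi]) and `r_squared`.
#' @export
pvaf <- function(gastric, rsn, n_trim = 15) {
  if (length(gastric) != length(rsn)) {
    stop("pvaf: series differ in length")
  }
  if (stats::sd(gastric) == 0 || stats::sd(rsn) == 0) {
    stop("pvaf: constant series has no variance to explain")
  }
  ag <- analytic_signal(gastric - mean(gastric))
  ar <- analytic_signal(rsn - mean(rsn))
  g <- trim_edges(gastric - mean(gastric), n_trim)
  ag <- trim_edges(ag, n_trim)
  ar <- trim_edges(ar, n_trim)
  delta_psi <- wrap_phase(Arg(ag) - Arg(ar))
  mu_hat <- estimate_phase_offset(delta_psi)
  rotated <- Re(ar * exp(1i * mu_hat))
  list(mu_hat = mu_hat, r_squared = stats::cor(g, rotated)^2)
}

#' Instantaneous phase of a run's gastric and filtered network signals
#'
#' Convenience wrapper used by the study-level analysis: filters every
#' network column with the run's BOLD-rate gastric bandpass, computes
#' analytic phases for the gastric signal and each network, and trims the
#' edges. By default the analytic transform runs on the full series and the
#' trim is applied to the phases, so the discarded volumes absorb the
#' transform's edge artifacts; set `trim_before_hilbert = TRUE` to trim the
#' filtered series first (sensitivity check).
#'
#' @param gastric a `gastric_signal`.
#' @param rsn_values time-by-network numeric matrix at the BOLD rate.
#' @param n_trim edge samples per end (default 15).
#' @param half_width,order_cycles bandpass parameters.
#' @param trim_before_hilbert logical; see above.
#' @return list with `gastric_phase` (vector), `rsn_phase` (matrix),
#'   `gastric_analytic`, `rsn_analytic` (trimmed analytic signals),
#'   `gastric_narrow`, `rsn_narrow` (trimmed narrowband series), and `spec`.
#' @export
run_phases <- function(gastric, rsn_values, n_trim = 15, half_width = 0.015,
                       order_cycles = 5, trim_before_hilbert = FALSE) {
  stopifnot(inherits(gastric, "gastric_signal"))
  rsn_values <- as.matrix(rsn_values)
  if (nrow(rsn_values) != length(gastric$values)) {
    stop("run_phases: RSN and gastric series differ in length")
  }
  spec <- rsn_bandpass_spec(gastric, half_width, order_cycles, gastric$rate)
  narrow <- apply(rsn_values, 2L, bandpass_rsn, spec = spec)
  analytic_of <- function(x) {
    if (trim_before_hilbert) analytic_signal(trim_edges(x, n_trim))
    else trim_edges(analytic_signal(x), n_trim)
  }
  a_g <- analytic_of(gastric$values)
  a_r <- apply(narrow, 2L, analytic_of)
  list(gastric_phase = wrap_phase(Arg(a_g)),
       rsn_phase = wrap_phase(Arg(a_r)),
       gastric_analytic = a_g, rsn_analytic = a_r,
       gastric_narrow = trim_edges(gastric$values, n_trim),
       rsn_narrow = apply(narrow, 2L, trim_edges, n_per_end = n_trim),
       spec = spec)
}
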