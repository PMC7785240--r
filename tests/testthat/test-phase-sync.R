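# Instantaneous phases, PLV, von Mises phase offset, and P.V.A.F.

test_that("RSN bandpass concentrates variance in the gastric band", {
  set.seed(21)
  spec <- design_gastric_bandpass(0.05, rate = 0.5)
  x <- rnorm(450)
  y <- bandpass_rsn(x, spec)
  mid <- trim_edges(y, 30)
  expect_gte(band_fraction(mid, 0.5, 0.035 - 0.004, 0.065 + 0.004), 0.8)
  # in-band tone passes with zero phase shift
  tt <- (0:449) * 2
  tone <- cos(2 * pi * 0.05 * tt)
  ft <- bandpass_rsn(tone, spec)
  mid_idx <- 100:350
  expect_lt(max(abs(wrap_phase(instantaneous_phase(ft)[mid_idx] -
                               instantaneous_phase(tone)[mid_idx]))), 0.01)
})

test_that("edge trimming follows the 15-volume rule", {
  expect_length(trim_edges(numeric(450)), 420L)   # 840 s at 0.5 Hz
  x <- rnorm(100)
  expect_identical(trim_edges(x, 0), x)
  expect_error(trim_edges(rnorm(30), 15), "not longer")
})

test_that("instantaneous phase advances like the underlying oscillation", {
  tt <- (0:449) * 2
  ph <- instantaneous_phase(cos(2 * pi * 0.05 * tt))
  inc <- wrap_phase(diff(ph))[50:400]
  expect_equal(mean(inc), 2 * pi * 0.05 * 2, tolerance = 1e-3)
  # sin lags cos by pi/2
  ph_sin <- instantaneous_phase(sin(2 * pi * 0.05 * tt))
  off <- wrap_phase(ph[50:400] - ph_sin[50:400])
  expect_equal(mean(off), pi / 2, tolerance = 1e-2)
  # amplitude does not matter (compare on the circle: +/- pi are one point)
  expect_lt(max(abs(wrap_phase(
    instantaneous_phase(3.2 * cos(2 * pi * 0.05 * tt)) - ph))), 1e-9)
  expect_error(instantaneous_phase(numeric(100)), "all-zero")
})

test_that("PLV honours its bounds, delay invariance, and symmetry", {
  set.seed(3)
  x <- runif(420, -pi, pi)
  y <- runif(420, -pi, pi)
  expect_equal(plv(x, x), 1, tolerance = 1e-12)
  expect_equal(plv(x, wrap_phase(x + 1.2)), 1, tolerance = 1e-12)
  v <- plv(x, y)
  expect_gte(v, 0)
  expect_lte(v, 1)
  expect_equal(plv(x, y), plv(y, x), tolerance = 1e-15)
  expect_error(plv(x, y[-1]), "length")
  # PLV = 1 exactly when the phase difference is constant; less otherwise
  expect_lt(plv(x, wrap_phase(x + c(rep(0, 210), rep(1, 210)))), 1)
})

test_that("the von Mises location estimate is the wrapping-correct circular mean", {
  expect_equal(estimate_phase_offset(rep(0.7, 10)), 0.7, tolerance = 1e-12)
  # two mass points straddling the cut average to +/- pi, not zero
  mu <- estimate_phase_offset(c(pi - 0.1, -(pi - 0.1)))
  expect_equal(abs(mu), pi, tolerance = 1e-9)
  # antisymmetry modulo the circle
  set.seed(4)
  d <- rvonmises(200, 0.9, 3)
  expect_equal(estimate_phase_offset(-d), -estimate_phase_offset(d),
               tolerance = 1e-12)
})

test_that("sampled von Mises draws recover their location against a grid-search oracle", {
  set.seed(5)
  d <- rvonmises(1000, mu = 1.0, kappa = 2)
  mu_hat <- estimate_phase_offset(d)
  expect_lt(abs(mu_hat - 1.0), 0.1)
  # independent oracle: maximize the von Mises log-likelihood over mu
  nll <- function(mu) -sum(cos(d - mu))
  grid <- seq(-pi, pi, length.out = 7200)
  g0 <- grid[which.min(vapply(grid, nll, 0))]
  opt <- stats::optimize(nll, c(g0 - 0.01, g0 + 0.01), tol = 1e-10)$minimum
  expect_lt(abs(mu_hat - opt), 1e-6)
})

test_that("P.V.A.F. is exact for linear relations and realigns lagged tones", {
  tt <- (0:449) * 2
  g <- cos(2 * pi * 0.05 * tt) + 0.0  # pure tone
  res <- pvaf(g, 2.5 * g)
  expect_equal(res$r_squared, 1, tolerance = 1e-6)
  expect_lt(abs(res$mu_hat), 1e-3)

  # quarter-cycle delay: nothing explained without rotation, nearly all with
  delayed <- cos(2 * pi * 0.05 * (tt - 5))
  raw_r2 <- cor(trim_edges(g, 15), trim_edges(delayed, 15))^2
  expect_lt(raw_r2, 0.05)
  res2 <- pvaf(g, delayed)
  expect_gte(res2$r_squared, 0.95)
  expect_equal(res2$mu_hat, pi / 2, tolerance = 0.05)

  # independent noise explains essentially nothing
  set.seed(6)
  res3 <- pvaf(g, rnorm(450))
  expect_lt(res3$r_squared, 0.05)
  expect_error(pvaf(g, rep(1, 450)), "variance")
})

test_that("run_phases wires filtering, phases, and trimming consistently", {
  set.seed(8)
  gas <- tone_gastric(0.05)
  rsn <- cbind(A = gas$values * 1.5 + rnorm(450, 0, 0.1),
               B = rnorm(450))
  ph <- run_phases(gas, rsn)
  expect_length(ph$gastric_phase, 420L)
  expect_equal(dim(ph$rsn_phase), c(420L, 2L))
  expect_gt(plv(ph$gastric_phase, ph$rsn_phase[, "A"]), 0.95)
  expect_lt(plv(ph$gastric_phase, ph$rsn_phase[, "B"]),
            plv(ph$gastric_phase, ph$rsn_phase[, "A"]))
  # the trim-first variant is available and produces the same shapes
  ph2 <- run_phases(gas, rsn, trim_before_hilbert = TRUE)
  expect_length(ph2$gastric_phase, 420L)
  expect_gt(plv(ph2$gastric_phase, ph2$rsn_phase[, "A"]), 0.9)
})
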