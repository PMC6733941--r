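test_that("multi-tau correlator basics: constant and uncorrelated traces", {
  expect_error(multitau_correlate(rep(0, 1000), 1e-4), "zero-mean")
  cv <- multitau_correlate(rep(7, 5000), 1e-4)
  expect_true(all(abs(cv$G - 1) < 1e-12))
  # independent Poisson bins: G(tau) = 1 within 3 SE for all tau > 0
  set.seed(8)
  x <- rpois(20000, 5)
  cvp <- multitau_correlate(x, 1e-4)
  se <- 1 / (sqrt(cvp$n_samples) * mean(x))  # var(G) ~ 1/(n <I>^2)
  expect_true(all(abs(cvp$G - 1) < 3.5 * se))
})

test_that("multi-tau equals the brute-force correlator at shared lags", {
  set.seed(9)
  x <- rpois(10000, 3)
  fast <- multitau_correlate(x, 1e-4, m_per_level = 8, n_levels = 5)
  slow <- naive_multitau(x, 1e-4, m_per_level = 8, n_levels = 5)
  expect_equal(nrow(fast), nrow(slow))
  expect_lt(max(abs(fast$G - slow$G) / slow$G), 1e-12)
  expect_equal(fast$lag_s, slow$lag_s)
})

test_that("FCS model fit round-trips analytic curves", {
  cv <- model_curve(N = 5, tau_D = 8e-3, Omega = 5)
  fit <- fit_fcs(cv)
  expect_true(fit$converged)
  expect_lt(abs(fit$N - 5) / 5, 1e-8)
  expect_lt(abs(fit$tau_D - 8e-3) / 8e-3, 1e-8)
  expect_lt(abs(fit$Omega - 5) / 5, 1e-6)
  # amplitude-occupancy relation: 1/N equals the short-lag amplitude
  expect_lt(abs(1 / fit$N - (cv$G[1] - 1)) / (cv$G[1] - 1), 0.05)
  # triplet round-trip
  cvt <- model_curve(N = 2, tau_D = 1e-3, Omega = 4.84, A_T = 0.25,
                     tau_T = 2e-6, span = c(1e-4, 1e3))
  fitt <- fit_fcs(cvt, fix_Omega = 4.84, fit_triplet = TRUE)
  expect_lt(abs(fitt$A_T - 0.25) / 0.25, 1e-6)
  expect_lt(abs(fitt$tau_T - 2e-6) / 2e-6, 1e-6)
})

test_that("Brownian simulation recovers the input diffusion time", {
  w <- 0.27e-6
  tau_D <- 1e-3
  p <- fcs_sim_params(D = w^2 / (4 * tau_D), mean_N = 2, omega_xy = w,
                      brightness = 5e4, duration = 20, bin_dt = 5e-5,
                      box_factor = 4)
  tr <- generate_fcs_trace(p, seed = 11)
  fit <- fit_fcs(multitau_correlate(tr), fix_Omega = p$Omega)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau_D - tau_D) / tau_D, 0.10)
  # amplitude: G(0) - 1 ~ 1/mean_N
  expect_lt(abs(fit$N - p$mean_N) / p$mean_N, 0.25)
})

test_that("telegraph blinking on an immobile emitter gives the triplet law", {
  # G = 1 + A_T exp(-tau/tau_T) for a blinking point source: validates the
  # triplet process in isolation (a joint diffusion run at 1 us binning
  # would be prohibitively long for the unit suite)
  p <- fcs_sim_params(D = 1e-30, mean_N = 1, brightness = 5e6, A_T = 0.3,
                      tau_T = 1e-6, duration = 0.5, bin_dt = 2e-7,
                      box_factor = 4)
  tr <- suppressWarnings(generate_fcs_trace(p, seed = 5,
                                            positions = matrix(0, 1, 3)))
  cv <- multitau_correlate(tr, n_levels = 8)
  d <- cv[cv$lag_s < 2e-5, ]
  fit <- nls(G ~ 1 + A * exp(-lag_s / tt), data = d,
             start = list(A = 0.2, tt = 1e-6))
  expect_lt(abs(coef(fit)[["A"]] - 0.3) / 0.3, 0.2)
  expect_lt(abs(coef(fit)[["tt"]] - 1e-6) / 1e-6, 0.2)
})

test_that("focal calibration reproduces the reference geometry", {
  tau_ref <- (0.27e-6)^2 / (4 * 4.6e-10)  # 39.6 us
  cv <- model_curve(N = 1.5, tau_D = tau_ref, Omega = 4.84)
  cal <- calibrate_focus(cv, D_ref = 4.6e-10, fix_Omega = 4.84)
  expect_equal(cal$omega_xy, 0.27e-6, tolerance = 1e-6)
  expect_equal(cal$V, 0.53e-18, tolerance = 0.01)  # 0.53 um^3
  # doubling D_ref at fixed curve scales omega by sqrt(2)
  cal2 <- calibrate_focus(cv, D_ref = 9.2e-10, fix_Omega = 4.84)
  expect_equal(cal2$omega_xy / cal$omega_xy, sqrt(2), tolerance = 1e-9)
})

test_that("diffusion, sizing and temperature corrections evaluate correctly", {
  expect_equal(diffusion_coefficient(39.6e-6, 0.27e-6), 4.60e-10,
               tolerance = 1e-3)
  D200 <- diffusion_coefficient(8e-3, 0.27e-6)
  expect_equal(D200, 2.278e-12, tolerance = 1e-3)
  expect_equal(diffusion_coefficient(1e-3, 2 * 0.27e-6) /
                 diffusion_coefficient(1e-3, 0.27e-6), 4)
  # 200 nm vesicles: hydrodynamic diameter ~215 nm
  expect_equal(2 * hydrodynamic_radius(D200, 298.15, 0.89e-3) * 1e9, 215.4,
               tolerance = 1e-3)
  expect_equal(hydrodynamic_radius(2 * D200) / hydrodynamic_radius(D200), 0.5)
  # small molecule sanity: Rhodamine 123 ~ 0.5 nm
  expect_equal(hydrodynamic_radius(4.6e-10) * 1e9, 0.53, tolerance = 0.05)
  # temperature correction
  expect_equal(correct_to_25C(1, 298.15), 1)
  expect_equal(correct_to_25C(1, 293.15), 1.144, tolerance = 1e-3)
  Ts <- seq(288, 308, by = 5)
  expect_true(all(diff(vapply(Ts, function(T) correct_to_25C(1, T),
                              numeric(1))) < 0))
})

test_that("titration slopes match the printed diffusion-time series", {
  # 200 nm series: baseline 8.0 ms with ~8% and ~18% increases
  s200 <- titration_slope(c(0, 0.1, 0.2), c(8000, 8640, 9440))
  expect_equal(s200$slope, 7200)
  expect_lt(abs(s200$slope - 7.0e3), 1.4e3)
  # 100 nm series: baseline 6.1 ms with ~13% and ~34% increases
  s100 <- titration_slope(c(0, 0.1, 0.2), c(6100, 6893, 8174))
  expect_equal(s100$slope, 10370)
  expect_lt(abs(s100$slope - 9.40e3), 1.4e3)
  expect_equal(titration_slope(c(0, 0.1, 0.2), rep(8000, 3))$slope, 0)
})

test_that("outlier curve rejection follows the batch statistics", {
  curves <- c(lapply(1:6, function(i) model_curve(N = 5, tau_D = 1e-3)),
              list(model_curve(N = 0.5, tau_D = 1e-3)))
  kept <- reject_outlier_curves(curves, fix_Omega = 4.84)
  expect_equal(attr(kept, "rejected"), 7L)
  expect_length(kept, 6)
  # homogeneous batch: nothing removed
  kept2 <- reject_outlier_curves(curves[1:6], fix_Omega = 4.84)
  expect_length(attr(kept2, "rejected"), 0)
  # batch of two: rejection disabled with a warning
  expect_warning(kept3 <- reject_outlier_curves(curves[1:2]), "disabled")
  expect_length(kept3, 2)
})
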