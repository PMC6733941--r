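test_that("noise-free trajectory follows the forward model exactly", {
  p <- fast_condition()
  tr <- generate_trajectory(p, noise = FALSE)
  E <- fret_trace(tr)
  # half-life definition: E at t0 + t_E is the midpoint of E0 and E_plateau
  i <- which.min(abs(tr$time - (p$t0 + p$t_E)))
  expect_equal(E[i], (0.46 + 0.22) / 2, tolerance = 1e-12)
  # pre-injection plateau
  pre <- tr$time < p$t0
  expect_true(all(abs(E[pre] - 0.46) < 1e-12))
  expect_true(all(abs(tr$donor[pre] + tr$acceptor[pre] - 200) < 1e-9))
  # long-time total intensity settles at (1 - f_loss) of the initial level
  expect_equal(tail(tr$donor + tr$acceptor, 1), 200 * 0.5, tolerance = 1e-3)
})

test_that("conservation: f_loss = 0 and no bleaching keeps total intensity", {
  p <- solub_params(f_loss = 0, duration = 400)
  tr <- generate_trajectory(p, noise = FALSE)
  expect_true(all(abs(tr$donor + tr$acceptor - p$I_tot0) < 1e-9))
  # and in expectation under Poisson noise: compare first/second half means
  trn <- generate_trajectory(p, seed = 1)
  tot <- trn$donor + trn$acceptor
  h <- length(tot) %/% 2
  se <- sd(tot) * sqrt(2 / h)
  expect_lt(abs(mean(tot[1:h]) - mean(tot[(h + 1):(2 * h)])), 3 * se)
})

test_that("Poisson noise has the law-of-large-numbers mean", {
  p <- solub_params(t0 = 60, duration = 120, background = 10)
  tr <- generate_trajectory(p, seed = 7)
  pre <- which(tr$time < p$t0)
  expect_gte(length(pre), 1000)
  mu <- (1 - p$E0) * p$I_tot0 + p$background
  se <- sqrt(mu / length(pre))
  expect_lt(abs(mean(tr$donor[pre]) - mu), 3 * se)
})

test_that("trajectory generator is seed-deterministic and validates input", {
  p <- fast_condition(duration = 120)
  expect_identical(generate_trajectory(p, seed = 3),
                   generate_trajectory(p, seed = 3))
  expect_false(identical(generate_trajectory(p, seed = 3)$donor,
                         generate_trajectory(p, seed = 4)$donor))
  expect_error(solub_params(E0 = 0.2, E_plateau = 0.4), "E_plateau")
  expect_error(solub_params(t_E = -1), "t_E")
  expect_error(solub_params(f_loss = 1.5), "f_loss")
  expect_error(generate_trajectory(p), "seed")
})

test_that("bleaching multiplies the expectation by exp(-rate * t)", {
  p <- solub_params(f_loss = 0, bleach_rate = 0.01, duration = 100)
  tr <- generate_trajectory(p, noise = FALSE)
  expect_equal(tr$donor + tr$acceptor, p$I_tot0 * exp(-0.01 * tr$time),
               tolerance = 1e-12)
})

test_that("noiseless titration matches the Hill model and round-trips", {
  h <- hill_params()
  tt <- generate_titration(h, noise_sd = 0)
  expect_equal(tt$E, hill_eval(tt$conc_mM, h), tolerance = 1e-15)
  # at c = k the response is the midpoint
  tk <- generate_titration(h, concentrations = c(0, h$k, 4.4), noise_sd = 0)
  expect_equal(tk$E[2], (h$A + h$B) / 2, tolerance = 1e-12)
  fit <- fit_hill(tt$conc_mM, tt$E)
  expect_lt(abs(fit$k - h$k) / h$k, 1e-6)
  expect_lt(abs(fit$n - h$n) / h$n, 1e-6)
  expect_lt(abs(fit$A - h$A) / h$A, 1e-6)
  expect_lt(abs(fit$B - h$B) / h$B, 1e-6)
})

test_that("titration noise is seed-deterministic Gaussian about the model", {
  h <- hill_params()
  t1 <- generate_titration(h, noise_sd = 0.01, replicates = 3, seed = 5)
  t2 <- generate_titration(h, noise_sd = 0.01, replicates = 3, seed = 5)
  expect_identical(t1, t2)
  resid <- t1$E - hill_eval(t1$conc_mM, h)
  expect_lt(abs(mean(resid)), 3 * 0.01 / sqrt(nrow(t1)))
})

test_that("QCM-D generator edge cases behave", {
  # no gain, no loss: flat at -f_vesicle
  q <- generate_qcmd_trace(qcmd_sim_params(gain_frac = 0, loss_frac = 0))
  expect_true(all(abs(q$delta_f_hz + 28) < 1e-12))
  # control: no vesicle layer at all
  qc <- generate_qcmd_trace(qcmd_sim_params(f_vesicle = 0))
  expect_true(all(qc$delta_f_hz == 0))
  # determinism with noise
  p <- qcmd_sim_params(noise_sd = 0.2)
  expect_identical(generate_qcmd_trace(p, seed = 2),
                   generate_qcmd_trace(p, seed = 2))
})

test_that("image stack renders exact integrated intensity per spot", {
  p <- solub_params(duration = 2, t0 = 1, frame_dt = 0.1, I_tot0 = 1000)
  tr <- generate_trajectory(p, noise = FALSE)
  st <- generate_image_stack(list(tr), rbind(c(20.4, 23.6)), psf_sigma = 1.5,
                             frame_shape = c(48, 48), background = 0,
                             noise = FALSE)
  # whole-frame sum equals the trajectory exactly (discrete normalization)
  frame_sums <- apply(st$donor, 3, sum)
  expect_equal(frame_sums, tr$donor, tolerance = 1e-9)
  # finite-aperture sum (4 sigma) captures the value within 1%
  msk <- vesolv:::circular_mask_idx(c(20.4, 23.6), 6, 48, 48)
  ap <- colSums(matrix(st$donor, 48 * 48, dim(st$donor)[3])[msk$lin, ])
  expect_true(all(abs(ap - tr$donor) / tr$donor < 0.01))
})

test_that("image stack generator checks geometry and is deterministic", {
  p <- solub_params(duration = 1, t0 = 0.5, frame_dt = 0.1)
  tr <- generate_trajectory(p, noise = FALSE)
  expect_error(generate_image_stack(list(tr), rbind(c(-3, 10)),
                                    frame_shape = c(32, 32), noise = FALSE),
               "within the frame")
  expect_warning(
    generate_image_stack(list(tr, tr), rbind(c(10, 10), c(10, 12)),
                         psf_sigma = 1.5, frame_shape = c(32, 32),
                         noise = FALSE),
    "overlap")
  s1 <- generate_image_stack(list(tr), rbind(c(16, 16)),
                             frame_shape = c(32, 32), seed = 9)
  s2 <- generate_image_stack(list(tr), rbind(c(16, 16)),
                             frame_shape = c(32, 32), seed = 9)
  expect_identical(s1$donor, s2$donor)
  # zero-intensity trajectory: background-only stack
  tr0 <- vesicle_trajectory(tr$time, tr$donor * 0, tr$acceptor * 0,
                            frame_dt = 0.1)
  s0 <- generate_image_stack(list(tr0), rbind(c(16, 16)),
                             frame_shape = c(32, 32), background = 3,
                             noise = FALSE)
  expect_true(all(s0$donor == 3))
})

test_that("FCS generator: immobile center particle gives flat Poisson trace", {
  p <- fcs_sim_params(D = 1e-30, mean_N = 1, brightness = 2e4,
                      duration = 4, bin_dt = 1e-4, box_factor = 4)
  tr <- suppressWarnings(
    generate_fcs_trace(p, seed = 3, positions = matrix(0, 1, 3)))
  mu <- 2e4 * 1e-4
  n <- length(tr$counts)
  expect_lt(abs(mean(tr$counts) - mu), 3 * sqrt(mu / n))
  # Poisson: variance approximately equals the mean
  expect_lt(abs(var(tr$counts) / mean(tr$counts) - 1), 0.1)
})

test_that("FCS generator mean count rate matches the occupancy factor", {
  # <rate> = brightness * mean_N * (integral of the Gaussian MDF over its
  # effective volume) = brightness * mean_N * 2^(-3/2)
  w <- 0.27e-6
  p <- fcs_sim_params(D = w^2 / (4 * 1e-3), mean_N = 2, omega_xy = w,
                      brightness = 5e4, duration = 10, bin_dt = 5e-5,
                      box_factor = 4)
  tr <- generate_fcs_trace(p, seed = 11)
  expected <- p$brightness * p$bin_dt * p$mean_N * 2^-1.5
  # counts are correlated over tau_D: use block means for the SE
  blocks <- split(tr$counts, cut(seq_along(tr$counts), 20))
  bm <- vapply(blocks, mean, numeric(1))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(tr$counts) - expected), 3 * se)
})

test_that("FCS generator warns on coarse binning and is deterministic", {
  w <- 0.27e-6
  p <- fcs_sim_params(D = w^2 / (4 * 1e-3), mean_N = 1, duration = 0.5,
                      bin_dt = 2e-4, box_factor = 3)
  expect_warning(generate_fcs_trace(p, seed = 1), "coarse")
  p2 <- fcs_sim_params(D = w^2 / (4 * 1e-3), mean_N = 1, duration = 0.5,
                       bin_dt = 4e-5, box_factor = 3)
  expect_identical(generate_fcs_trace(p2, seed = 5)$counts,
                   generate_fcs_trace(p2, seed = 5)$counts)
})

test_that("trajectory and FCS trace CSV round-trips preserve data", {
  p <- fast_condition(duration = 100)
  tr <- generate_trajectory(p, seed = 2)
  f <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$donor, tr$donor)
  expect_equal(attr(tr2, "t0"), attr(tr, "t0"))
  w <- 0.27e-6
  pf <- fcs_sim_params(D = w^2 / 4e-3 / 4, mean_N = 1, duration = 0.2,
                       bin_dt = 5e-5, box_factor = 3)
  ftr <- generate_fcs_trace(pf, seed = 1)
  f2 <- file.path(tempdir(), "fcs.csv")
  write_fcs_trace(ftr, f2)
  ftr2 <- read_fcs_trace(f2)
  expect_equal(ftr2$counts, as.integer(ftr$counts))
  expect_equal(ftr2$bin_dt, ftr$bin_dt)
})
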