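test_that("noiseless biphasic fit recovers generator half-lives exactly", {
  tr <- generate_trajectory(fast_condition(), noise = FALSE)
  fit <- fit_biphasic(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$t_E - 1.2) / 1.2, 1e-6)
  expect_lt(abs(fit$t_L - 17.6) / 17.6, 1e-6)
  # amplitude mapping: baseline is the pre-injection donor level,
  # offset the long-time donor level
  expect_equal(fit$baseline, (1 - 0.46) * 200, tolerance = 1e-6)
  expect_equal(fit$offset, (1 - 0.22) * 200 * 0.5, tolerance = 1e-4)
  expect_equal(fit$f_loss, 0.5, tolerance = 1e-6)
})

test_that("biphasic fit is invariant to intensity rescaling", {
  tr <- generate_trajectory(fast_condition(), noise = FALSE)
  tr10 <- vesicle_trajectory(tr$time, 10 * tr$donor, 10 * tr$acceptor,
                             frame_dt = attr(tr, "frame_dt"),
                             t0 = attr(tr, "t0"))
  f1 <- fit_biphasic(tr)
  f10 <- fit_biphasic(tr10)
  expect_lt(abs(f10$t_E - f1$t_E) / f1$t_E, 1e-9)
  expect_lt(abs(f10$t_L - f1$t_L) / f1$t_L, 1e-9)
  expect_equal(f10$A_rise, 10 * f1$A_rise, tolerance = 1e-6)
  expect_equal(f10$A_decay, 10 * f1$A_decay, tolerance = 1e-6)
})

test_that("additive fit form round-trips additive data", {
  t <- seq(0.05, 200, by = 0.05)
  s <- pmax(t - 50, 0)
  donor <- 100 + 60 * (1 - 2^(-s / 2)) + 90 * (2^(-s / 30) - 1)
  tr <- vesicle_trajectory(t, donor, donor * 0 + 50, frame_dt = 0.05, t0 = 50)
  fit <- fit_biphasic(tr, form = "additive")
  expect_true(fit$converged)
  expect_lt(abs(fit$t_E - 2) / 2, 1e-6)
  expect_lt(abs(fit$t_L - 30) / 30, 1e-6)
  expect_equal(fit$A_rise, 60, tolerance = 1e-6)
  expect_equal(fit$A_decay, 90, tolerance = 1e-6)
})

test_that("degenerate trace without lysis flags t_L as unidentifiable", {
  p <- solub_params(t_E = 1.2, t_L = 17.6, f_loss = 1e-9, duration = 300)
  tr <- generate_trajectory(p, noise = FALSE)
  fit <- fit_biphasic(tr)
  expect_true(any(grepl("t_L unidentifiable", fit$flags)))
})

test_that("ensemble recovery at the fast condition matches within uncertainty", {
  # scaled-down ensemble (30 trajectories) for the unit suite; the full
  # 100-trajectory run lives in the acceptance tests
  fits <- lapply(1:30, function(i) {
    fit_biphasic(generate_trajectory(fast_condition(), seed = i))
  })
  ok <- vapply(fits, `[[`, logical(1), "converged")
  expect_gte(mean(ok), 0.9)
  tE <- vapply(fits[ok], `[[`, numeric(1), "t_E")
  tL <- vapply(fits[ok], `[[`, numeric(1), "t_L")
  expect_lt(abs(mean(tE) - 1.2), 0.4)   # printed +/- 0.4 s
  expect_lt(abs(mean(tL) - 17.6), 1.6)  # printed +/- 1.6 s
})

test_that("injection detection finds t0 and rejects constant traces", {
  tr <- generate_trajectory(fast_condition(), seed = 201)
  expect_lt(abs(detect_injection(tr) - 90), 1)
  const <- vesicle_trajectory(seq(0.05, 10, 0.05),
                              rep(100, 200), rep(100, 200), frame_dt = 0.05)
  expect_error(detect_injection(const), "no change-point")
  # a step at the very first frame maps to the first frame time
  step <- vesicle_trajectory(seq(0.05, 10, 0.05),
                             c(100, rep(500, 199)), rep(100, 200),
                             frame_dt = 0.05)
  expect_equal(detect_injection(step), 0.05)
})

test_that("phase segmentation matches the closed-form swelling drop", {
  tr <- generate_trajectory(fast_condition(), noise = FALSE)
  fit <- fit_biphasic(tr)
  seg <- segment_phases(tr, fit)
  # over [t0, t0 + 3 t_E] the efficiency falls by (E0 - Ep) (1 - 2^-3)
  expect_equal(seg$summary$dE_swelling, -(0.46 - 0.22) * (1 - 2^-3),
               tolerance = 1e-3)
  expect_equal(unname(seg$boundaries["swelling_end"]), 90 + 3 * 1.2,
               tolerance = 1e-4)
  expect_identical(levels(seg$labels), c("pre", "swelling", "lysis", "post"))
  expect_false(is.unsorted(as.integer(seg$labels)))
  # intensity loss during the fast swelling window is small (few percent)
  expect_lt(abs(seg$summary$pct_I_swelling), 15)
  # no lysis -> no intensity change over the lysis window
  p0 <- solub_params(f_loss = 0, t_E = 1.2, t_L = 17.6, duration = 300)
  tr0 <- generate_trajectory(p0, noise = FALSE)
  seg0 <- segment_phases(tr0, fit_biphasic(tr0))
  expect_lt(abs(seg0$summary$pct_I_lysis), 0.5)
  # refuse a non-converged fit
  bad <- fit
  bad$converged <- FALSE
  expect_error(segment_phases(tr, bad), "refused")
})

test_that("FRET contour columns are normalized and track the population", {
  # single constant-E trajectory: unit mass in one E bin per column
  tr <- vesicle_trajectory(seq(1, 100), rep(55, 100), rep(45, 100),
                           frame_dt = 1)
  ct <- build_fret_contour(list(tr), time_bin_s = 10)
  expect_true(all(abs(colSums(ct) - 1) < 1e-12))
  expect_true(all(apply(ct, 2, max) == 1))
  # population contour: modal E moves from ~0.46 (pre) to ~0.22 (late)
  trajs <- lapply(1:20, function(i) {
    generate_trajectory(fast_condition(), seed = 300 + i)
  })
  ct2 <- build_fret_contour(trajs, time_bin_s = 10, e_bin_width = 0.02)
  expect_true(all(abs(colSums(ct2) - 1) < 1e-12))
  modal <- as.numeric(rownames(ct2))[apply(ct2, 2, which.max)]
  expect_lt(abs(modal[2] - 0.46), 0.03)
  expect_lt(abs(modal[ncol(ct2)] - 0.22), 0.03)
  expect_error(build_fret_contour(list()), "empty")
})

test_that("condition summaries and comparisons reproduce constructed ratios", {
  mkfits <- function(tE, tL, n = 12) {
    lapply(seq_len(n), function(i) {
      p <- solub_params(t_E = tE, t_L = tL, duration = 60 + 8 * tL, t0 = 30)
      fit_biphasic(generate_trajectory(p, noise = FALSE))
    })
  }
  # lysis 12x slower than expansion by construction
  s1 <- summarize_condition(mkfits(2, 24, n = 3), "chol20/0.08mM")
  expect_equal(s1$ratio_L_over_E, 12, tolerance = 1e-4)
  # half-lives scaled by 0.24 : a 76% reduction
  s2 <- summarize_condition(mkfits(2 * 0.24, 24 * 0.24, n = 3), "chol0/0.08mM")
  cmp <- compare_conditions(list(s1, s2))
  row <- cmp$pairwise[cmp$pairwise$condition_a == "chol0/0.08mM", ]
  expect_equal(row$pct_change_t_E, -76, tolerance = 1e-3)
  expect_equal(row$pct_change_t_L, -76, tolerance = 1e-3)
  # identical conditions: zero change
  cmp0 <- compare_conditions(list(s1, transform(s1, label = "dup")))
  expect_equal(cmp0$pairwise$pct_change_t_E, c(0, 0), tolerance = 1e-9)
  expect_error(compare_conditions(list(s1, s1)), "distinct")
})

test_that("half-life / time-constant conversions are mutually inverse", {
  expect_equal(tau_to_halflife(halflife_to_tau(17.6)), 17.6)
  expect_equal(halflife_to_tau(log(2)), 1)
})
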