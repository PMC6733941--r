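#' Multi-tau autocorrelation of a photon-count trace
#'
#' Standard logarithmic-lag correlator: `m_per_level` linear lags at the raw
#' bin width, then `m_per_level / 2` new lags per level with the bin width
#' doubling each level (adjacent bins averaged). The estimator is
#' `G(tau) = <I(t) I(t+tau)> / (<I_head> <I_tail>)` with symmetric
#' normalization (head/tail means computed over the actually overlapping
#' samples), so an uncorrelated signal gives `G = 1`.
#'
#' @param counts Numeric/integer count trace (or an `fcs_trace`).
#' @param bin_dt Bin width (s); taken from the trace when `counts` is an
#'   `fcs_trace`.
#' @param m_per_level Lags per level (even; default 16).
#' @param n_levels Maximum number of levels; capped automatically when the
#'   trace is too short.
#' @return An `fcs_correlation` data frame: `lag_s`, `G`, `n_samples`
#'   (number of averaged products at the level's bin width).
#' @export
multitau_correlate <- function(counts, bin_dt = NULL, m_per_level = 16,
                               n_levels = 20) {
  if (inherits(counts, "fcs_trace")) {
    bin_dt <- counts$bin_dt
    counts <- counts$counts
  }
  check_positive(bin_dt, "bin_dt")
  if (m_per_level < 4 || m_per_level %% 2 != 0) {
    stop_invalid("`m_per_level` must be an even number >= 4")
  }
  x <- as.numeric(counts)
  if (mean(x) == 0) stop_invalid("zero-mean trace: correlation normalization undefined")
  w <- bin_dt
  lag_s <- G <- ns <- numeric(0)
  for (level in seq_len(n_levels) - 1L) {
    n <- length(x)
    ks <- if (level == 0L) seq_len(m_per_level) else
      seq(m_per_level / 2 + 1, m_per_level)
    if (n <= max(ks) + 1) break
    for (k in ks) {
      h <- x[seq_len(n - k)]
      tl <- x[seq(k + 1, n)]
      G <- c(G, mean(h * tl) / (mean(h) * mean(tl)))
      lag_s <- c(lag_s, k * w)
      ns <- c(ns, n - k)
    }
    n2 <- n %/% 2L
    if (n2 <= m_per_level + 1) break
    x <- (x[2 * seq_len(n2) - 1L] + x[2 * seq_len(n2)]) / 2
    w <- 2 * w
  }
  structure(data.frame(lag_s = lag_s, G = G, n_samples = ns),
            class = c("fcs_correlation", "data.frame"))
}

#' Analytic FCS model: 3D diffusion with optional triplet term
#'
#' `G(tau) = 1 + b0 + (1/N) (1 + tau/tau_D)^-1 (1 + tau/(Omega^2 tau_D))^-1/2
#' (1 + A_T exp(-tau/tau_T))`, the open 3D Gaussian-volume diffusion model
#' with a triplet blinking factor. The leading 1 is the uncorrelated
#' baseline of the normalization used by [multitau_correlate()].
#'
#' @param lag Lag times (s).
#' @param N Mean focal-volume occupancy.
#' @param tau_D Diffusion time (s).
#' @param Omega Structure parameter (axial/radial 1/e^2 ratio).
#' @param A_T Triplet amplitude (0 = no triplet).
#' @param tau_T Triplet time (s).
#' @param b0 Residual baseline offset.
#' @return `G` values at `lag`.
#' @export
fcs_model <- function(lag, N, tau_D, Omega = 4.84, A_T = 0, tau_T = 1e-6,
                      b0 = 0) {
  1 + b0 + (1 / N) * (1 + lag / tau_D)^-1 *
    (1 + lag / (Omega^2 * tau_D))^-0.5 *
    (1 + A_T * exp(-lag / tau_T))
}

#' Fit the 3D-diffusion (+ triplet) model to a correlation curve
#'
#' Weighted nonlinear least squares with per-lag weights equal to
#' `n_samples` (i.e. a per-lag standard deviation proportional to
#' `n_samples^(-1/2)`). Initial guesses: `N` from the short-lag amplitude
#' `1/(G(tau_min) - 1)`, `tau_D` from the lag where the amplitude halves.
#' Triplet terms are fitted only when `fit_triplet = TRUE`; the baseline
#' `b0` is fixed at 0 unless `fit_b0 = TRUE`.
#'
#' @param curve An `fcs_correlation` (or any data frame with `lag_s`, `G`
#'   and optionally `n_samples`).
#' @param fix_Omega Fix the structure parameter at this value instead of
#'   fitting it (recommended when the curve poorly constrains the axial
#'   ratio). `NULL` fits it.
#' @param fit_triplet Include the triplet factor.
#' @param fit_b0 Fit the residual baseline.
#' @param Omega_start Start value when `Omega` is fitted.
#' @return An `fcs_fit` object: `N`, `tau_D`, `Omega`, `A_T`, `tau_T`, `b0`,
#'   `stderr` (named), `chi2_reduced`, `converged`, `flags`.
#' @export
fit_fcs <- function(curve, fix_Omega = NULL, fit_triplet = FALSE,
                    fit_b0 = FALSE, Omega_start = 5) {
  df <- as.data.frame(curve)[, intersect(c("lag_s", "G", "n_samples"),
                                         names(curve)), drop = FALSE]
  stopifnot(all(c("lag_s", "G") %in% names(df)))
  df <- df[order(df$lag_s), , drop = FALSE]
  wts <- if ("n_samples" %in% names(df)) df$n_samples else rep(1, nrow(df))
  amp0 <- max(df$G[1] - 1, 1e-6)
  N0 <- 1 / amp0
  half_idx <- which(df$G - 1 <= amp0 / 2)
  tD0 <- if (length(half_idx)) df$lag_s[half_idx[1]] else median(df$lag_s)

  rhs <- "1 %s + (1/N) * (1 + lag_s/tD)^-1 * (1 + lag_s/(%s^2*tD))^-0.5 %s"
  om <- if (is.null(fix_Omega)) "Om" else format(fix_Omega, digits = 15)
  b0s <- if (fit_b0) "+ b0" else ""
  trip <- if (fit_triplet) "* (1 + AT*exp(-lag_s/tT))" else ""
  form <- stats::as.formula(paste("G ~", sprintf(rhs, b0s, om, trip)))

  start <- list(N = N0, tD = tD0)
  lower <- c(N = 1e-12, tD = min(df$lag_s) / 100)
  upper <- c(N = Inf, tD = max(df$lag_s) * 100)
  if (is.null(fix_Omega)) {
    start$Om <- Omega_start; lower <- c(lower, Om = 1.01); upper <- c(upper, Om = 100)
  }
  if (fit_triplet) {
    start$AT <- 0.2; start$tT <- tD0 / 50
    lower <- c(lower, AT = 0, tT = min(df$lag_s) / 100)
    upper <- c(upper, AT = 20, tT = max(df$lag_s))
  }
  if (fit_b0) {
    start$b0 <- 0; lower <- c(lower, b0 = -1); upper <- c(upper, b0 = 1)
  }

  try_fit <- function(st) {
    tryCatch(
      suppressWarnings(
        nls(form, data = df, start = st, weights = wts,
            algorithm = "port", lower = lower[names(st)],
            upper = upper[names(st)],
            control = nls.control(maxiter = 500, warnOnly = TRUE))),
      error = function(e) e
    )
  }
  fit <- try_fit(start)
  if (fit_triplet) {
    # the triplet time is prone to degenerate local minima; multi-start it
    rss <- function(f) {
      if (inherits(f, "error")) Inf else sum(wts * (df$G - predict(f))^2)
    }
    for (tT0 in min(df$lag_s) * c(10, 100, 1000)) {
      st <- start
      st$tT <- tT0
      cand <- try_fit(st)
      if (rss(cand) < rss(fit) * (1 - 1e-10)) fit <- cand
    }
  }
  if (inherits(fit, "error")) {
    return(structure(list(N = NA_real_, tau_D = NA_real_,
                          Omega = fix_Omega %||% NA_real_, A_T = NA_real_,
                          tau_T = NA_real_, b0 = 0, stderr = NULL,
                          chi2_reduced = NA_real_, converged = FALSE,
                          flags = c("non-convergence", conditionMessage(fit))),
                     class = "fcs_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    setNames(rep(NA_real_, length(cf)), names(cf))
  })
  res <- df$G - predict(fit)
  chi2r <- sum(wts * res^2) / max(nrow(df) - length(cf), 1)
  flags <- character()
  tau_T <- if (fit_triplet) unname(cf["tT"]) else NA_real_
  tau_D <- unname(cf["tD"])
  if (fit_triplet && tau_T >= tau_D / 2) {
    warning("fitted triplet time >= tau_D/2: triplet/diffusion mixing",
            call. = FALSE)
    flags <- c(flags, "triplet/diffusion mixing")
  }
  structure(
    list(N = unname(cf["N"]), tau_D = tau_D,
         Omega = if (is.null(fix_Omega)) unname(cf["Om"]) else fix_Omega,
         A_T = if (fit_triplet) unname(cf["AT"]) else 0,
         tau_T = tau_T,
         b0 = if (fit_b0) unname(cf["b0"]) else 0,
         stderr = se, chi2_reduced = chi2r,
         converged = isTRUE(fit$convInfo$isConv), flags = flags),
    class = "fcs_fit"
  )
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("<fcs_fit>", if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  N = %.4g, tau_D = %.4g s, Omega = %.3g", x$N, x$tau_D, x$Omega))
  if (x$A_T > 0) cat(sprintf(", A_T = %.3g, tau_T = %.3g s", x$A_T, x$tau_T))
  cat(sprintf("  (chi2_red = %.3g)\n", x$chi2_reduced))
  invisible(x)
}

#' Calibrate the focal volume from a reference-dye correlation curve
#'
#' Fits the reference curve, then `omega_xy = sqrt(4 D_ref tau_D_ref)` and
#' `V = pi^(3/2) * Omega * omega_xy^3` (effective Gaussian volume).
#'
#' @param reference_curve `fcs_correlation` measured on a dye of known
#'   diffusion coefficient (Rhodamine 123 here, `D = 4.6e-10 m^2/s`).
#' @param D_ref Reference diffusion coefficient (m^2/s).
#' @param fix_Omega Optionally fix the structure parameter during the fit.
#' @param ... Further arguments for [fit_fcs()].
#' @return A `focal_calibration`: `omega_xy` (m), `Omega`, `V` (m^3),
#'   `D_ref`, plus the underlying `fit`.
#' @export
calibrate_focus <- function(reference_curve, D_ref = 4.6e-10,
                            fix_Omega = NULL, ...) {
  check_positive(D_ref, "D_ref")
  fit <- fit_fcs(reference_curve, fix_Omega = fix_Omega, ...)
  if (!fit$converged) warning("reference fit did not converge", call. = FALSE)
  omega_xy <- sqrt(4 * D_ref * fit$tau_D)
  structure(list(omega_xy = omega_xy, Omega = fit$Omega,
                 V = pi^1.5 * fit$Omega * omega_xy^3,
                 D_ref = D_ref, fit = fit),
            class = "focal_calibration")
}

#' Diffusion coefficient from diffusion time
#'
#' `D = omega_xy^2 / (4 tau_D)`.
#'
#' @param tau_D Diffusion time (s).
#' @param omega_xy Radial 1/e^2 focus radius (m).
#' @return Diffusion coefficient (m^2/s).
#' @export
diffusion_coefficient <- function(tau_D, omega_xy = 0.27e-6) {
  if (any(tau_D <= 0)) stop_invalid("`tau_D` must be positive")
  check_positive(omega_xy, "omega_xy")
  omega_xy^2 / (4 * tau_D)
}

#' Stokes-Einstein hydrodynamic radius
#'
#' `R_h = k_B T / (6 pi eta D)`.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @param T_K Temperature (K).
#' @param eta Dynamic viscosity (Pa s); default water at 25 C.
#' @return Hydrodynamic radius (m).
#' @export
hydrodynamic_radius <- function(D, T_K = 298.15, eta = 8.90e-4) {
  if (any(D <= 0)) stop_invalid("`D` must be positive")
  check_positive(T_K, "T_K")
  check_positive(eta, "eta")
  .kB * T_K / (6 * pi * eta * D)
}

#' Dynamic viscosity of water
#'
#' Vogel-type correlation `eta = 2.414e-5 * 10^(247.8/(T - 140))` Pa s,
#' accurate to ~1% between 0 and 100 C (gives 1.002 mPa s at 20 C and
#' 0.891 mPa s at 25 C).
#'
#' @param T_K Temperature (K).
#' @return Viscosity (Pa s).
#' @export
water_viscosity <- function(T_K) {
  if (any(T_K <= 140)) stop_invalid("temperature out of range")
  2.414e-5 * 10^(247.8 / (T_K - 140))
}

#' Correct a diffusion coefficient to 25 C
#'
#' Stokes-Einstein scaling `D_25 = D * (298.15/T) * (eta(T)/eta(298.15))`
#' with the water-viscosity correlation (the Tris buffer is treated as
#' water-like).
#'
#' @param D_measured Measured diffusion coefficient (m^2/s).
#' @param T_measured Measurement temperature (K).
#' @return Diffusion coefficient referenced to 25 C.
#' @export
correct_to_25C <- function(D_measured, T_measured) {
  check_positive(T_measured, "T_measured")
  D_measured * (298.15 / T_measured) *
    (water_viscosity(T_measured) / water_viscosity(298.15))
}

#' Linear fit of diffusion time against detergent concentration
#'
#' Ordinary least squares through `(concentration, tau_D)` points, as used to
#' compare the detergent-induced swelling of different vesicle sizes.
#'
#' @param conc_mM Concentrations (mM).
#' @param tau_D_us Diffusion times (microseconds).
#' @return List: `slope` (us/mM), `stderr`, `intercept_us`, and the `lm` fit.
#' @export
titration_slope <- function(conc_mM, tau_D_us) {
  stopifnot(length(conc_mM) == length(tau_D_us), length(conc_mM) >= 2)
  fit <- lm(tau_D_us ~ conc_mM)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["conc_mM", "Estimate"]),
       stderr = unname(cf["conc_mM", "Std. Error"]),
       intercept_us = unname(cf["(Intercept)", "Estimate"]),
       fit = fit)
}

#' Exclude correlation curves distorted by aggregate transits
#'
#' Fits every curve and drops those whose occupancy `N` deviates more than
#' `n_mad` MADs from the batch median or whose reduced chi-square exceeds
#' `chi2_max` times the batch median chi-square (the weighted chi-square has
#' no absolute scale because per-lag variances are only known up to a
#' constant). With two or fewer curves the statistics are meaningless and
#' rejection is disabled with a warning.
#'
#' @param curves List of `fcs_correlation` objects.
#' @param n_mad MAD multiple for the occupancy criterion.
#' @param chi2_max Reduced chi-square ceiling.
#' @param ... Arguments passed to [fit_fcs()] (e.g. `fix_Omega`).
#' @return The retained curves; attributes `rejected` (indices) and `fits`.
#' @export
reject_outlier_curves <- function(curves, n_mad = 3, chi2_max = 5, ...) {
  if (length(curves) <= 2) {
    warning("batch of <= 2 curves: outlier rejection disabled", call. = FALSE)
    return(structure(curves, rejected = integer(0), fits = NULL))
  }
  fits <- lapply(curves, fit_fcs, ...)
  Ns <- vapply(fits, `[[`, numeric(1), "N")
  chi <- vapply(fits, `[[`, numeric(1), "chi2_reduced")
  medN <- median(Ns, na.rm = TRUE)
  # floor the MAD so a batch of identical (noise-free) curves still rejects
  # a deviating one instead of disabling the criterion
  madN <- max(mad(Ns, na.rm = TRUE), 1e-6 * abs(medN) + 1e-12)
  med_chi <- median(chi, na.rm = TRUE)
  bad <- (!is.na(Ns) & abs(Ns - medN) > n_mad * madN) |
    (!is.na(chi) & med_chi > 0 & chi > chi2_max * med_chi) | is.na(Ns)
  structure(curves[!bad], rejected = which(bad), fits = fits)
}
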