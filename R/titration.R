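#' Ensemble FRET efficiency from donor/acceptor emission bands
#'
#' `E = I_665 / (I_665 + I_565)` from the acceptor (665 nm) and donor
#' (565 nm) emission intensities. When full spectra are supplied, band
#' intensities are integrated over `band_halfwidth` nm either side of each
#' band center (trapezoidal rule).
#'
#' @param I_565,I_665 Donor- and acceptor-band intensities, vectorized.
#' @return Efficiency in `[0, 1]` (`NA` when both bands are zero).
#' @examples
#' ensemble_fret(57, 43)  # 0.43, the zero-detergent value
#' @export
ensemble_fret <- function(I_565, I_665) {
  apparent_fret(I_565, I_665)
}

#' @rdname ensemble_fret
#' @param wavelength,intensity Emission spectrum (nm, arbitrary units).
#' @param donor_band,acceptor_band Band centers (nm).
#' @param band_halfwidth Half-width of the integration bands (nm).
#' @export
ensemble_fret_spectrum <- function(wavelength, intensity,
                                   donor_band = 565, acceptor_band = 665,
                                   band_halfwidth = 5) {
  stopifnot(length(wavelength) == length(intensity))
  band <- function(center) {
    sel <- wavelength >= center - band_halfwidth &
      wavelength <= center + band_halfwidth
    if (sum(sel) < 2) stop_invalid("spectrum does not cover the %g nm band", center)
    w <- wavelength[sel]
    y <- intensity[sel]
    sum(diff(w) * (head(y, -1) + tail(y, -1)) / 2)
  }
  ensemble_fret(band(donor_band), band(acceptor_band))
}

#' Evaluate the Hill dose-response model
#'
#' `E(c) = A + (B - A) * c^n / (k^n + c^n)`: `E(0) = A`, `E -> B` as
#' `c -> Inf`, and `E(k) = (A + B)/2`. The interpolating form is used so that
#' `A` and `B` are the titration endpoints.
#'
#' @param conc Detergent concentration (mM), vectorized, non-negative.
#' @param fit A [hill_params()] or fitted [fit_hill()] object.
#' @return Efficiency vector.
#' @examples
#' hill_eval(0, hill_params())     # 0.43
#' hill_eval(0.39, hill_params())  # (0.43 + 0.12)/2
#' @export
hill_eval <- function(conc, fit) {
  p <- as_hill_list(fit)
  if (any(conc < 0)) stop_invalid("`conc` must be non-negative")
  h <- ifelse(conc == 0, 0, conc^p$n / (p$k^p$n + conc^p$n))
  p$A + (p$B - p$A) * h
}

as_hill_list <- function(fit) {
  if (inherits(fit, "hill_fit")) {
    list(A = fit$A, B = fit$B, k = fit$k, n = fit$n)
  } else if (inherits(fit, "hill_params") || (is.list(fit) &&
             all(c("A", "B", "k", "n") %in% names(fit)))) {
    fit
  } else {
    stop_invalid("`fit` must be a hill_params or hill_fit object")
  }
}

#' Generate synthetic ensemble-FRET titration data
#'
#' Draws efficiencies as Hill-model means plus i.i.d. Gaussian noise.
#'
#' @param hill A [hill_params()] (or fitted [fit_hill()]) generating model.
#' @param concentrations Concentration grid (mM). Default: 0 plus nine
#'   log-spaced points from 0.05 to 4.4 mM, bracketing the half-maximal
#'   constant of the reference titration.
#' @param noise_sd Gaussian noise standard deviation (efficiency units).
#' @param replicates Replicate measurements per concentration.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Data frame with columns `conc_mM`, `replicate`, `E`.
#' @export
generate_titration <- function(hill = hill_params(),
                               concentrations = default_titration_grid(),
                               noise_sd = 0.01, replicates = 1, seed = NULL) {
  check_nonneg(noise_sd, "noise_sd")
  stopifnot(replicates >= 1)
  mu <- hill_eval(concentrations, hill)
  df <- data.frame(
    conc_mM = rep(concentrations, times = replicates),
    replicate = rep(seq_len(replicates), each = length(concentrations)),
    E = rep(mu, times = replicates)
  )
  if (noise_sd > 0) {
    if (is.null(seed)) stop_invalid("`seed` is required when `noise_sd > 0`")
    df$E <- with_seed(seed, df$E + rnorm(nrow(df), sd = noise_sd))
  }
  df
}

#' @rdname generate_titration
#' @export
default_titration_grid <- function() {
  c(0, exp(seq(log(0.05), log(4.4), length.out = 9)))
}

#' Fit the Hill model to titration data
#'
#' Nonlinear least squares (port algorithm) for the interpolating Hill model.
#' Initial guesses: `A` from the lowest-concentration mean, `B` from the
#' highest, `k` the median concentration, `n = 1`. Parameter standard errors
#' come from the fit covariance.
#'
#' @param conc Concentrations (mM); should include 0 and extend well past the
#'   expected half-maximal constant.
#' @param E Measured efficiencies, same length.
#' @param weights Optional nls weights.
#' @return A `hill_fit` object: fields `A`, `B`, `k`, `n`, `stderr` (named),
#'   `chi2`, `converged` and `flags`.
#' @export
fit_hill <- function(conc, E, weights = NULL) {
  stopifnot(length(conc) == length(E))
  if (length(unique(conc)) < 3) {
    stop_invalid("need at least 3 distinct concentrations")
  }
  df <- data.frame(c = conc, E = E)
  ord <- order(conc)
  A0 <- mean(E[conc == min(conc)])
  B0 <- mean(E[conc == max(conc)])
  start <- list(A = A0, B = B0, k = median(conc[conc > 0]), n = 1)
  flags <- character()
  fit <- tryCatch(
    nls(E ~ A + (B - A) * ifelse(c == 0, 0, c^n / (k^n + c^n)),
        data = df, start = start, weights = weights,
        algorithm = "port",
        lower = c(A = 0, B = 0, k = 1e-8, n = 1e-3),
        upper = c(A = 1, B = 1, k = Inf, n = 50),
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(A = NA_real_, B = NA_real_, k = NA_real_,
                          n = NA_real_, stderr = NULL, chi2 = NA_real_,
                          converged = FALSE,
                          flags = c("non-convergence", conditionMessage(fit))),
                     class = "hill_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  # an essentially flat titration leaves n (and k) unconstrained
  if (!is.na(se["n"]) && (se["n"] > 10 || abs(cf["A"] - cf["B"]) < 4 * sd(E - mean(E)) / sqrt(length(E)))) {
    flags <- c(flags, "n unidentifiable (no concentration trend)")
  }
  res <- df$E - predict(fit)
  structure(
    list(A = unname(cf["A"]), B = unname(cf["B"]), k = unname(cf["k"]),
         n = unname(cf["n"]), stderr = se,
         chi2 = sum(res^2), converged = TRUE, flags = flags),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>\n")
  if (x$converged) {
    cat(sprintf("  A = %.4f, B = %.4f, k = %.4f mM, n = %.3f (chi2 = %.3g)\n",
                x$A, x$B, x$k, x$n, x$chi2))
  } else {
    cat("  fit did not converge\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
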