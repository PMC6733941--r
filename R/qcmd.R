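#' Generate a synthetic QCM-D solubilization trace
#'
#' Piecewise frequency-shift trace (relative to the bare sensor): a stable
#' vesicle-layer baseline at `-f_vesicle`, an exponential-ramp gain phase to
#' `-f_vesicle * (1 + gain_frac)` (detergent uptake), a plateau while intact
#' vesicles rearrange without mass transfer, then an exponential relaxation
#' to `-f_vesicle * (1 + gain_frac) * (1 - loss_frac)` (lysis).
#' Ramps are truncated exponentials normalized to complete exactly at the
#' phase boundary, so noiseless traces round-trip through
#' [detect_mass_phases()] to machine precision. Dissipation is proportional
#' to the frequency deviation from the bare sensor (soft-layer caricature)
#' and Gaussian noise is added to both channels.
#'
#' @param params A [qcmd_sim_params()] object.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A `qcmd_trace`: data frame `time_s`, `delta_f_hz`, `delta_D`
#'   (1e-6 convention) with the overtone and truth parameters as attributes.
#' @export
generate_qcmd_trace <- function(params, seed = NULL) {
  stopifnot(inherits(params, "qcmd_sim_params"))
  p <- params
  t <- seq(0, p$duration, by = p$dt)
  t1 <- p$injection_time
  t2 <- t1 + p$gain_duration
  t3 <- t2 + p$hold_duration
  f_base <- -p$f_vesicle
  f_peak <- -p$f_vesicle * (1 + p$gain_frac)
  f_final <- f_peak * (1 - p$loss_frac)
  # half-life style ramp normalized to reach exactly 1 at the phase end
  ramp <- function(s, tau, span) (1 - 2^(-s / tau)) / (1 - 2^(-span / tau))
  f <- numeric(length(t))
  pre <- t < t1
  gain <- t >= t1 & t < t2
  hold <- t >= t2 & t < t3
  loss <- t >= t3
  f[pre] <- f_base
  f[gain] <- f_base + (f_peak - f_base) * ramp(t[gain] - t1, p$tau_gain, t2 - t1)
  f[hold] <- f_peak
  f[loss] <- f_peak + (f_final - f_peak) *
    ramp(t[loss] - t3, p$tau_loss, max(p$duration - t3, p$dt))
  dD <- -p$dissipation_scale * f
  if (p$noise_sd > 0) {
    if (is.null(seed)) stop_invalid("`seed` is required when `noise_sd > 0`")
    noise <- with_seed(seed, list(f = rnorm(length(t), sd = p$noise_sd),
                                  d = rnorm(length(t), sd = p$noise_sd *
                                              p$dissipation_scale)))
    f <- f + noise$f
    dD <- dD + noise$d
  }
  qcmd_trace(t, f, dD, overtone = p$overtone, truth = unclass(p))
}

#' Construct a QCM-D trace object
#'
#' @param time_s Time (s).
#' @param delta_f_hz Frequency shift at the chosen overtone (Hz), relative to
#'   the bare sensor.
#' @param delta_D Dissipation shift (1e-6 convention); optional.
#' @param overtone Odd harmonic number.
#' @param truth Optional generating parameters.
#' @return A `qcmd_trace` data frame.
#' @export
qcmd_trace <- function(time_s, delta_f_hz, delta_D = rep(0, length(time_s)),
                       overtone = 7, truth = NULL) {
  if (length(delta_f_hz) != length(time_s) || length(delta_D) != length(time_s)) {
    stop_invalid("columns must have equal length")
  }
  if (overtone %% 2 != 1 || overtone < 1) stop_invalid("`overtone` must be odd and >= 1")
  structure(
    data.frame(time_s = time_s, delta_f_hz = delta_f_hz, delta_D = delta_D),
    overtone = overtone, truth = truth,
    class = c("qcmd_trace", "data.frame")
  )
}

#' Sauerbrey areal mass from a frequency shift
#'
#' `delta_m = -C * delta_f / n`: a frequency decrease maps to a positive
#' areal mass. Valid for thin rigid films; vesicle layers are viscoelastic,
#' so treat the result as an effective (Sauerbrey) mass.
#'
#' @param delta_f Frequency shift (Hz), vectorized.
#' @param overtone Odd harmonic number `n`.
#' @param C Quartz mass-sensitivity constant (ng Hz^-1 cm^-2).
#' @return Areal mass change (ng/cm^2).
#' @examples
#' sauerbrey_mass(-7, overtone = 7)  # +17.7 ng/cm^2
#' @export
sauerbrey_mass <- function(delta_f, overtone = 7, C = 17.7) {
  if (overtone %% 2 != 1 || overtone < 1) {
    stop_invalid("`overtone` must be an odd integer >= 1 (got %g)", overtone)
  }
  check_positive(C, "C")
  -C * delta_f / overtone
}

#' Detect mass-gain and mass-loss phases in a QCM-D trace
#'
#' Converts the frequency trace to Sauerbrey mass, then: the vesicle-layer
#' mass `m_vesicle` is the mean over the baseline window; the peak mass
#' `m_peak` is the maximum after injection on a 5-point median-filtered
#' series; the final mass `m_final` is the mean over the terminal window.
#' Percent gain is referenced to the vesicle-layer mass and percent loss to
#' the peak mass. A gain phase is only declared when the peak exceeds the
#' baseline by 3 baseline noise SDs. A soft-film warning fires when the
#' dissipation-to-frequency ratio exceeds `4e-7` per Hz (Sauerbrey
#' underestimates mass for such layers).
#'
#' @param trace A `qcmd_trace` (columns `time_s`, `delta_f_hz`, optional
#'   `delta_D`; overtone attribute or `overtone` argument).
#' @param baseline_window Length-2 time window (s) preceding injection.
#' @param injection_time Injection time (s).
#' @param terminal_frac Final fraction of the trace averaged for `m_final`.
#' @param C Sauerbrey constant (ng Hz^-1 cm^-2).
#' @param overtone Overtone override.
#' @return A `mass_phase_result`: `m_vesicle`, `m_peak`, `m_final` (ng/cm^2),
#'   `gain_pct`, `loss_pct`, `t_peak`, `t_settle` (first time within 5% of
#'   the final mass after the peak), `flags`.
#' @export
detect_mass_phases <- function(trace, baseline_window = NULL, injection_time,
                               terminal_frac = 0.05, C = 17.7,
                               overtone = NULL) {
  overtone <- overtone %||% attr(trace, "overtone") %||% 7
  t <- trace$time_s
  m <- sauerbrey_mass(trace$delta_f_hz, overtone = overtone, C = C)
  baseline_window <- baseline_window %||% c(min(t), injection_time)
  if (baseline_window[2] > injection_time) {
    stop_invalid("baseline window must precede the injection")
  }
  base_sel <- t >= baseline_window[1] & t < baseline_window[2]
  if (sum(base_sel) < 2) stop_invalid("baseline window too short")
  m_vesicle <- mean(m[base_sel])
  noise_sd <- sd(m[base_sel])
  post <- which(t >= injection_time)
  if (length(post) < 5) stop_invalid("too few samples after injection")
  msm <- m
  msm[post] <- runmed(m[post], 5)
  ipk <- post[which.max(msm[post])]
  m_peak <- msm[ipk]
  n_term <- max(2L, ceiling(terminal_frac * length(t)))
  m_final <- mean(tail(m, n_term))
  flags <- character()

  if (!is.null(trace$delta_D) && any(trace$delta_f_hz < 0)) {
    sel <- trace$delta_f_hz < -abs(noise_sd) * 3 - 1e-12
    if (any(sel)) {
      ratio <- median(abs(trace$delta_D[sel] * 1e-6) /
                        abs(trace$delta_f_hz[sel] / overtone))
      if (is.finite(ratio) && ratio > 4e-7) {
        warning("high dissipation/frequency ratio: soft film, Sauerbrey mass is a lower bound",
                call. = FALSE)
        flags <- c(flags, "soft-film regime")
      }
    }
  }

  no_layer <- abs(m_vesicle) <= max(3 * noise_sd, 1e-9)
  gain_detected <- m_peak > m_vesicle + max(3 * noise_sd, 1e-9 * max(abs(m_vesicle), 1))
  if (no_layer) {
    flags <- c(flags, "no vesicle layer: phases not defined")
    gain_pct <- 0
    loss_pct <- 0
    gain_detected <- FALSE
  } else {
    gain_pct <- if (gain_detected) 100 * (m_peak - m_vesicle) / m_vesicle else 0
    if (!gain_detected) {
      flags <- c(flags, "no gain phase detected")
      m_peak <- m_vesicle
    }
    loss_pct <- 100 * (m_peak - m_final) / m_peak
  }
  cand <- post[post >= ipk]
  settle <- cand[abs(msm[cand] - m_final) <= 0.05 * abs(m_peak - m_final) + 1e-12]
  structure(
    list(m_vesicle = m_vesicle, m_peak = m_peak, m_final = m_final,
         gain_pct = gain_pct, loss_pct = loss_pct,
         t_peak = t[ipk],
         t_settle = if (length(settle)) t[settle[1]] else NA_real_,
         noise_sd = noise_sd, gain_detected = gain_detected,
         flags = flags),
    class = "mass_phase_result"
  )
}

#' @export
print.mass_phase_result <- function(x, ...) {
  cat("<mass_phase_result>\n")
  cat(sprintf("  m_vesicle = %.4g, m_peak = %.4g, m_final = %.4g ng/cm^2\n",
              x$m_vesicle, x$m_peak, x$m_final))
  cat(sprintf("  gain = %.3g%%, loss = %.3g%% (peak at %g s)\n",
              x$gain_pct, x$loss_pct, x$t_peak))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Paired frequency-dissipation series for D-f plots
#'
#' Time-ordered `(delta_f, delta_D)` pairs; consecutive duplicate pairs are
#' collapsed (a constant trace reduces to a single point) and an optional
#' decimation factor thins dense traces.
#'
#' @param trace A `qcmd_trace`.
#' @param decimate Keep every `decimate`-th sample (default 1 = all).
#' @return Data frame `delta_f_hz`, `delta_D`, `time_s`.
#' @export
df_plot_data <- function(trace, decimate = 1) {
  stopifnot(decimate >= 1)
  idx <- seq(1, nrow(trace), by = decimate)
  df <- data.frame(delta_f_hz = trace$delta_f_hz[idx],
                   delta_D = trace$delta_D[idx],
                   time_s = trace$time_s[idx])
  dup <- c(FALSE, diff(df$delta_f_hz) == 0 & diff(df$delta_D) == 0)
  df[!dup, , drop = FALSE]
}

#' Write / read QCM-D traces as CSV
#'
#' Columns `time_s`, `delta_f_hz`, `delta_D`, `overtone`.
#'
#' @param trace A `qcmd_trace`.
#' @param path CSV path.
#' @return `write_qcmd_trace` returns `path` invisibly; `read_qcmd_trace`
#'   returns a `qcmd_trace`.
#' @export
write_qcmd_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  df$overtone <- attr(trace, "overtone")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qcmd_trace
#' @export
read_qcmd_trace <- function(path) {
  df <- read.csv(path)
  qcmd_trace(df$time_s, df$delta_f_hz, df$delta_D %||% rep(0, nrow(df)),
             overtone = df$overtone[1] %||% 7)
}
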