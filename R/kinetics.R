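#' Fit the biphasic solubilization model to a donor trajectory
#'
#' The donor channel rises as the FRET efficiency drops during swelling and
#' subsequently falls as lipid (and dye) is lost during lysis. Two fit forms
#' are offered, both parameterized directly in half-lives (base-2
#' exponentials, so `t_E` and `t_L` are true half-lives):
#'
#' * `"mechanistic"` (default): the forward-model donor expectation
#'   `I_D(t) = baseline * (1 + (rho - 1) * (1 - 2^(-s/t_E))) *
#'   (1 - f * (1 - 2^(-s/t_L)))` with `s = t - t0`, i.e. the product of a
#'   saturating rise (swelling acts on the efficiency only) and a decay
#'   (lysis acts on the total intensity only). Noiseless synthetic
#'   trajectories are recovered exactly under this form.
#' * `"additive"`: `I_D(t) = baseline + A_rise * (1 - 2^(-s/t_E)) +
#'   A_decay * (2^(-s/t_L) - 1)`, the sum-of-exponentials convention. It
#'   cannot represent the rise-decay cross term, so recovery from the forward
#'   model is approximate (bias well below the noise level for separated
#'   timescales).
#'
#' Only frames with `t >= t0` enter the fit. Initial guesses: `t_E` at 5% and
#' `t_L` at 50% of the fit window, amplitudes from the trace extrema; both
#' half-lives are bounded to `[frame_dt, 10 * window]`.
#'
#' @param traj A [vesicle_trajectory()].
#' @param t0 Injection time (s); defaults to the trajectory's `t0` attribute,
#'   or [detect_injection()] when absent.
#' @param form Fit form, see Details.
#' @return A `biphasic_fit` object with fields `t0`, `t_E`, `t_L`, `baseline`
#'   (pre-injection donor level), `A_rise`, `A_decay`, `offset` (long-time
#'   donor level), `f_loss` (mechanistic form), `stderr`, `chi2_reduced`,
#'   `converged` and `flags`.
#' @export
fit_biphasic <- function(traj, t0 = NULL, form = c("mechanistic", "additive")) {
  stopifnot(inherits(traj, "vesicle_trajectory"))
  form <- match.arg(form)
  t0 <- t0 %||% attr(traj, "t0") %||% detect_injection(traj)
  frame_dt <- attr(traj, "frame_dt")
  post <- traj$time >= t0
  if (sum(post) < 20) stop_invalid("need at least 20 frames after t0")
  s <- traj$time[post] - t0
  y <- traj$donor[post]
  W <- max(s)

  sm <- if (length(y) >= 5) runmed(y, 5) else y
  b0 <- max(mean(head(y, 5)), 1e-9)
  peak <- max(sm)
  final <- mean(tail(sm, max(5L, length(sm) %/% 20L)))
  tE0 <- 0.05 * W
  tL0 <- 0.5 * W
  lo_t <- frame_dt
  hi_t <- 10 * W
  df <- data.frame(s = s, y = y)

  if (form == "mechanistic") {
    r0 <- max(peak / b0, 1 + 1e-3)
    f0 <- min(max(1 - final / (b0 * r0), 1e-3), 0.999)
    fit <- tryCatch(
      nls(y ~ b * (1 + (r - 1) * (1 - 2^(-s / tE))) * (1 - f * (1 - 2^(-s / tL))),
          data = df,
          start = list(b = b0, r = r0, f = f0, tE = tE0, tL = tL0),
          algorithm = "port",
          lower = c(b = 1e-12, r = 1e-6, f = 0, tE = lo_t, tL = lo_t),
          upper = c(b = Inf, r = Inf, f = 1, tE = hi_t, tL = hi_t),
          control = nls.control(maxiter = 500, warnOnly = TRUE)),
      error = function(e) e
    )
  } else {
    Ar0 <- max(peak - b0, 1e-6)
    Ad0 <- max(peak - final, 1e-6)
    fit <- tryCatch(
      nls(y ~ b + Ar * (1 - 2^(-s / tE)) + Ad * (2^(-s / tL) - 1),
          data = df,
          start = list(b = b0, Ar = Ar0, Ad = Ad0, tE = tE0, tL = tL0),
          algorithm = "port",
          lower = c(b = -Inf, Ar = 0, Ad = 0, tE = lo_t, tL = lo_t),
          upper = c(b = Inf, Ar = Inf, Ad = Inf, tE = hi_t, tL = hi_t),
          control = nls.control(maxiter = 500, warnOnly = TRUE)),
      error = function(e) e
    )
  }

  if (inherits(fit, "error")) {
    return(structure(list(t0 = t0, t_E = NA_real_, t_L = NA_real_,
                          baseline = NA_real_, A_rise = NA_real_,
                          A_decay = NA_real_, offset = NA_real_,
                          f_loss = NA_real_, stderr = NULL,
                          chi2_reduced = NA_real_, converged = FALSE,
                          form = form,
                          flags = c("non-convergence", conditionMessage(fit))),
                     class = "biphasic_fit"))
  }

  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    setNames(rep(NA_real_, length(cf)), names(cf))
  })
  res <- df$y - predict(fit)
  chi2r <- sum(res^2) / max(length(res) - length(cf), 1)
  converged <- fit$convInfo$isConv %||% TRUE
  flags <- character()

  if (form == "mechanistic") {
    baseline <- unname(cf["b"])
    A_rise <- baseline * (unname(cf["r"]) - 1)
    A_decay <- baseline * unname(cf["r"]) * unname(cf["f"])
    offset <- baseline * unname(cf["r"]) * (1 - unname(cf["f"]))
    f_loss <- unname(cf["f"])
    # near-zero loss fraction: the decay half-life has no signal to bind to
    decay_small <- f_loss < 1e-4
  } else {
    baseline <- unname(cf["b"])
    A_rise <- unname(cf["Ar"])
    A_decay <- unname(cf["Ad"])
    offset <- baseline + A_rise - A_decay
    f_loss <- NA_real_
    decay_small <- A_decay < 1e-6 * max(abs(baseline), 1)
  }
  tE <- unname(cf["tE"])
  tL <- unname(cf["tL"])
  if (decay_small) flags <- c(flags, "t_L unidentifiable (no decay amplitude)")
  at_bound <- tE <= lo_t * (1 + 1e-8) || tE >= hi_t * (1 - 1e-8) ||
    tL <= lo_t * (1 + 1e-8) || tL >= hi_t * (1 - 1e-8)
  if (at_bound && !decay_small) {
    flags <- c(flags, "half-life at fit bound")
    converged <- FALSE
  }
  if (!converged) flags <- c(flags, "nls reported non-convergence")
  if (tE > tL) flags <- c(flags, "atypical: expansion slower than lysis")

  structure(
    list(t0 = t0, t_E = tE, t_L = tL, baseline = baseline,
         A_rise = A_rise, A_decay = A_decay, offset = offset,
         f_loss = f_loss, stderr = se, chi2_reduced = chi2r,
         converged = converged, form = form, flags = flags),
    class = "biphasic_fit"
  )
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("<biphasic_fit>", if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  t_E = %.4g s, t_L = %.4g s (t0 = %g s, %s form)\n",
              x$t_E, x$t_L, x$t0, x$form))
  cat(sprintf("  baseline = %.4g, A_rise = %.4g, A_decay = %.4g, offset = %.4g\n",
              x$baseline, x$A_rise, x$A_decay, x$offset))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Convert half-lives to e-folding time constants and back
#'
#' Fits in this package report base-2 half-lives directly; these helpers
#' convert to/from exponential time constants (`t_half = tau * ln 2`) for
#' comparison with plain-exponential conventions.
#'
#' @param t_half Half-life.
#' @param tau Exponential time constant.
#' @return The converted value.
#' @export
halflife_to_tau <- function(t_half) t_half / log(2)

#' @rdname halflife_to_tau
#' @export
tau_to_halflife <- function(tau) tau * log(2)

#' Detect the detergent-injection time on the donor channel
#'
#' Change-point rule: the first time the `window`-frame rolling mean of the
#' donor departs more than `threshold` rolling-mean standard deviations from
#' the expanding pre-window mean. The per-frame noise scale is the robust
#' `mad(diff(donor))/sqrt(2)` so slow drifts do not inflate it.
#'
#' @param traj A [vesicle_trajectory()].
#' @param window Rolling-mean window (frames).
#' @param threshold Departure threshold in rolling-mean SDs.
#' @return Injection time (s): the time of the last pre-departure frame.
#' @export
detect_injection <- function(traj, window = 10, threshold = 5) {
  y <- traj$donor
  n <- length(y)
  if (n <= window) stop_invalid("trajectory shorter than detection window")
  sigma <- mad(diff(y)) / sqrt(2)
  sigma_m <- max(sigma, 1e-12 * max(abs(y), 1)) / sqrt(window)
  csum <- cumsum(y)
  for (i in seq(window + 1L, n)) {
    m <- (csum[i] - csum[i - window]) / window
    mu_pre <- csum[i - window] / (i - window)
    if (abs(m - mu_pre) > threshold * sigma_m) {
      return(traj$time[i - window])
    }
  }
  stop_invalid("no change-point detected")
}

#' Segment a trajectory into pre / swelling / lysis / post phases
#'
#' Phase boundaries are placed at three half-lives (~88% completion):
#' swelling spans `[t0, t0 + 3 t_E]`, lysis `(t0 + 3 t_E, t0 + 3 t_E + 3 t_L]`.
#' Summary statistics (efficiency change over swelling, percent
#' total-intensity change over each window) are read off 5-frame
#' median-filtered traces.
#'
#' @param traj A [vesicle_trajectory()].
#' @param fit A converged [fit_biphasic()] result.
#' @return A `phase_segmentation` object: `labels` (factor per frame, levels
#'   pre/swelling/lysis/post), `boundaries` (named times), and `summary`
#'   (`dE_swelling`, `pct_I_swelling`, `pct_I_lysis`).
#' @export
segment_phases <- function(traj, fit) {
  stopifnot(inherits(fit, "biphasic_fit"))
  if (!fit$converged) stop_invalid("segmentation refused: fit did not converge")
  t0 <- fit$t0
  b1 <- t0 + 3 * fit$t_E
  b2 <- b1 + 3 * fit$t_L
  labels <- cut(traj$time,
                breaks = c(-Inf, t0, b1, b2, Inf),
                labels = c("pre", "swelling", "lysis", "post"),
                right = FALSE)
  E <- fret_trace(traj)
  I <- traj$donor + traj$acceptor
  k <- min(5L, length(E) - (1 - length(E) %% 2))
  Em <- runmed(E, k)
  Im <- runmed(I, k)
  at <- function(tt) which.min(abs(traj$time - min(tt, max(traj$time))))
  i0 <- at(t0); i1 <- at(b1); i2 <- at(b2)
  summary <- list(
    dE_swelling = Em[i1] - Em[i0],
    pct_I_swelling = 100 * (Im[i1] - Im[i0]) / Im[i0],
    pct_I_lysis = 100 * (Im[i2] - Im[i1]) / Im[i1]
  )
  structure(list(labels = labels,
                 boundaries = c(t0 = t0, swelling_end = b1, lysis_end = b2),
                 summary = summary),
            class = "phase_segmentation")
}

#' Population FRET contour matrix
#'
#' Histograms the per-frame FRET efficiencies of many vesicles into time and
#' efficiency bins; every time-bin column is normalized to unit mass, giving
#' the relative occupancy of efficiency states over time.
#'
#' @param trajectories List of [vesicle_trajectory()] objects.
#' @param time_bin_s Time bin width (s).
#' @param e_bin_width Efficiency bin width (efficiency spans `[0, 1]`).
#' @return A matrix (rows: efficiency bins, columns: time bins) with bin
#'   centers as dimnames, class `fret_contour`; attributes `e_breaks`,
#'   `time_breaks`.
#' @export
build_fret_contour <- function(trajectories, time_bin_s = 10, e_bin_width = 0.02) {
  if (length(trajectories) == 0) stop_invalid("empty trajectory list")
  tt <- unlist(lapply(trajectories, `[[`, "time"))
  EE <- unlist(lapply(trajectories, fret_trace))
  keep <- !is.na(EE)
  tt <- tt[keep]; EE <- pmin(pmax(EE[keep], 0), 1)
  if (!length(tt)) stop_invalid("no defined FRET samples")
  e_breaks <- seq(0, 1, by = e_bin_width)
  if (e_breaks[length(e_breaks)] < 1) e_breaks <- c(e_breaks, 1)
  t_breaks <- seq(0, max(tt) + time_bin_s, by = time_bin_s)
  ei <- findInterval(EE, e_breaks, rightmost.closed = TRUE, all.inside = TRUE)
  ti <- findInterval(tt, t_breaks, rightmost.closed = TRUE, all.inside = TRUE)
  m <- matrix(0, nrow = length(e_breaks) - 1, ncol = length(t_breaks) - 1)
  for (j in seq_along(ei)) m[ei[j], ti[j]] <- m[ei[j], ti[j]] + 1
  cs <- colSums(m)
  nonzero <- cs > 0
  m[, nonzero] <- sweep(m[, nonzero, drop = FALSE], 2, cs[nonzero], "/")
  m <- m[, nonzero, drop = FALSE]
  dimnames(m) <- list(
    E = sprintf("%.3f", (head(e_breaks, -1) + tail(e_breaks, -1)) / 2),
    time_s = sprintf("%.1f", ((head(t_breaks, -1) + tail(t_breaks, -1)) / 2)[nonzero])
  )
  structure(m, e_breaks = e_breaks, time_breaks = t_breaks[c(TRUE, nonzero)],
            class = c("fret_contour", "matrix", "array"))
}

#' Summarize biphasic fits for one experimental condition
#'
#' @param fits List of [fit_biphasic()] results (non-converged fits are
#'   dropped with a message).
#' @param label Condition label, e.g. `"0% chol / 0.16 mM TX-100"`.
#' @return A one-row data frame of class `condition_summary`: `label`, `n`,
#'   `mean_t_E`, `sem_t_E`, `mean_t_L`, `sem_t_L`, `ratio_L_over_E`.
#' @export
summarize_condition <- function(fits, label) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop_invalid("no converged fits for condition '%s'", label)
  if (any(!ok)) message(sum(!ok), " non-converged fit(s) dropped")
  tE <- vapply(fits[ok], `[[`, numeric(1), "t_E")
  tL <- vapply(fits[ok], `[[`, numeric(1), "t_L")
  n <- sum(ok)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  structure(
    data.frame(label = label, n = n,
               mean_t_E = mean(tE), sem_t_E = sem(tE),
               mean_t_L = mean(tL), sem_t_L = sem(tL),
               ratio_L_over_E = mean(tL) / mean(tE)),
    class = c("condition_summary", "data.frame")
  )
}

#' Compare condition summaries
#'
#' Builds pairwise percent changes `100 * (a - b) / b` of the mean half-lives
#' between all ordered pairs of conditions, plus the per-condition
#' lysis/expansion ratios.
#'
#' @param summaries List of [summarize_condition()] rows with distinct labels.
#' @return List with `conditions` (stacked summaries) and `pairwise`
#'   (data frame: `condition_a`, `condition_b`, `pct_change_t_E`,
#'   `pct_change_t_L`).
#' @export
compare_conditions <- function(summaries) {
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  if (anyDuplicated(df$label)) stop_invalid("condition labels must be distinct")
  pairs <- expand.grid(a = seq_len(nrow(df)), b = seq_len(nrow(df)))
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  pw <- data.frame(
    condition_a = df$label[pairs$a],
    condition_b = df$label[pairs$b],
    pct_change_t_E = 100 * (df$mean_t_E[pairs$a] - df$mean_t_E[pairs$b]) /
      df$mean_t_E[pairs$b],
    pct_change_t_L = 100 * (df$mean_t_L[pairs$a] - df$mean_t_L[pairs$b]) /
      df$mean_t_L[pairs$b]
  )
  list(conditions = df, pairwise = pw)
}
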