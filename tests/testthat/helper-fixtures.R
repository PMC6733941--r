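# Shared fixtures and independent oracles for the test suite.

# Reference condition: no-cholesterol vesicles at doubled TX-100, the
# fastest-solubilizing condition (t_E = 1.2 s, t_L = 17.6 s).
fast_condition <- function(duration = 300, ...) {
  solub_params(t_E = 1.2, t_L = 17.6, E0 = 0.46, E_plateau = 0.22,
               f_loss = 0.5, I_tot0 = 200, t0 = 90, frame_dt = 0.05,
               duration = duration, ...)
}

# Brute-force multi-tau oracle: plain loops, same estimator definition as
# multitau_correlate (bin-doubling coarsening, symmetric normalization).
naive_multitau <- function(counts, bin_dt, m_per_level = 16, n_levels = 20) {
  x <- as.numeric(counts)
  w <- bin_dt
  out <- data.frame(lag_s = numeric(0), G = numeric(0))
  for (level in seq_len(n_levels) - 1L) {
    n <- length(x)
    ks <- if (level == 0L) 1:m_per_level else (m_per_level / 2 + 1):m_per_level
    if (n <= max(ks) + 1) break
    for (k in ks) {
      num <- 0
      mh <- 0
      mt <- 0
      for (t in 1:(n - k)) {
        num <- num + x[t] * x[t + k]
        mh <- mh + x[t]
        mt <- mt + x[t + k]
      }
      num <- num / (n - k)
      mh <- mh / (n - k)
      mt <- mt / (n - k)
      out <- rbind(out, data.frame(lag_s = k * w, G = num / (mh * mt)))
    }
    n2 <- n %/% 2L
    if (n2 <= m_per_level + 1) break
    xx <- numeric(n2)
    for (t in 1:n2) xx[t] <- (x[2 * t - 1] + x[2 * t]) / 2
    x <- xx
    w <- 2 * w
  }
  out
}

# Deterministic, well-separated spot layout on a grid with jitter.
spot_grid <- function(n, frame = 128, margin = 12, pitch = 24, seed = 42) {
  g <- expand.grid(r = seq(margin, frame - margin, by = pitch),
                   c = seq(margin, frame - margin, by = pitch))
  stopifnot(nrow(g) >= n)
  set.seed(seed)
  jit <- matrix(runif(2 * n, -0.45, 0.45), ncol = 2)
  cbind(g$r[seq_len(n)], g$c[seq_len(n)]) + jit
}

# Analytic correlation curve for round-trip fits.
model_curve <- function(N, tau_D, Omega = 4.84, A_T = 0, tau_T = 1e-6,
                        n_pts = 120, span = c(1e-4, 1e3)) {
  lags <- exp(seq(log(span[1] * tau_D), log(span[2] * tau_D),
                  length.out = n_pts))
  data.frame(lag_s = lags,
             G = fcs_model(lags, N, tau_D, Omega, A_T, tau_T),
             n_samples = rep(1, n_pts))
}
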