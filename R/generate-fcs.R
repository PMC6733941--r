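#' Simulate an FCS photon-count trace by Brownian dynamics
#'
#' Particles diffuse in a periodic box whose half-widths are
#' `box_factor * omega_xy` laterally and `box_factor * omega_z` axially
#' (large enough to avoid edge depletion at the default `box_factor = 8`).
#' The particle count is chosen so the mean occupancy of the effective focal
#' volume `pi^(3/2) * Omega * omega_xy^3` equals `mean_N`; per-bin expected
#' counts are `brightness * bin_dt * sum_i exp(-2 r_i^2/omega_xy^2 -
#' 2 z_i^2/omega_z^2)` and observed counts are Poisson. With `A_T > 0` each
#' particle additionally blinks via a two-state telegraph process
#' (equilibrium dark fraction `A_T/(1 + A_T)`, correlation time `tau_T`).
#'
#' @param params An [fcs_sim_params()] object.
#' @param seed Integer seed (all randomness flows through one seeded
#'   generator; identical `params` + `seed` give identical counts).
#' @param positions Optional matrix (n x 3, meters) of initial particle
#'   positions; overrides the occupancy-derived particle number. Used e.g. to
#'   pin a single immobile emitter at the focus center.
#' @return An `fcs_trace` object: list with `counts` (integer per bin),
#'   `bin_dt`, `n_particles` and the generating `params`.
#' @export
generate_fcs_trace <- function(params, seed, positions = NULL) {
  stopifnot(inherits(params, "fcs_sim_params"))
  p <- params
  tau_D <- p$omega_xy^2 / (4 * p$D)
  if (p$D > 0 && p$bin_dt > tau_D / 20) {
    warning(sprintf(
      "bin_dt = %g s is coarse relative to the diffusion time %g s (> tau_D/20)",
      p$bin_dt, tau_D), call. = FALSE)
  }
  omega_z <- p$Omega * p$omega_xy
  Lxy <- p$box_factor * p$omega_xy
  Lz <- p$box_factor * omega_z
  V_eff <- pi^1.5 * p$Omega * p$omega_xy^3
  V_box <- (2 * Lxy)^2 * (2 * Lz)
  n_bins <- floor(p$duration / p$bin_dt)
  if (n_bins < 2) stop_invalid("duration too short for the given bin_dt")
  step_sd <- sqrt(2 * p$D * p$bin_dt)
  amp <- p$brightness * p$bin_dt
  p_dark <- if (p$A_T > 0) p$A_T / (1 + p$A_T) else 0
  counts <- with_seed(seed, {
    if (is.null(positions)) {
      n_particles <- max(1L, round(p$mean_N * V_box / V_eff))
      positions <- cbind(runif(n_particles, -Lxy, Lxy),
                         runif(n_particles, -Lxy, Lxy),
                         runif(n_particles, -Lz, Lz))
    } else {
      positions <- as.matrix(positions)
      stopifnot(ncol(positions) == 3)
    }
    fcs_sim_cpp(n_bins, positions, step_sd, Lxy, Lz,
                p$omega_xy, omega_z, amp, p_dark, p$tau_T, p$bin_dt)
  })
  structure(list(counts = counts, bin_dt = p$bin_dt,
                 n_particles = nrow(positions), params = p),
            class = "fcs_trace")
}

#' @export
print.fcs_trace <- function(x, ...) {
  cat(sprintf(
    "<fcs_trace> %d bins of %g s (%.3g s), %d particles, mean rate %.3g kHz\n",
    length(x$counts), x$bin_dt, length(x$counts) * x$bin_dt,
    x$n_particles, mean(x$counts) / x$bin_dt / 1000))
  invisible(x)
}

#' Write / read an FCS count trace as CSV plus JSON sidecar
#'
#' @param trace An `fcs_trace`.
#' @param path CSV path (single `counts` column; `bin_dt` and the truth
#'   parameters go into `<path>.json`).
#' @return `write_fcs_trace` returns `path` invisibly; `read_fcs_trace`
#'   returns an `fcs_trace`.
#' @export
write_fcs_trace <- function(trace, path) {
  write.csv(data.frame(counts = trace$counts), path, row.names = FALSE)
  jsonlite::write_json(
    list(bin_dt = trace$bin_dt, n_particles = trace$n_particles,
         truth = unclass(trace$params)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fcs_trace
#' @export
read_fcs_trace <- function(path) {
  counts <- read.csv(path)$counts
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(counts = counts, bin_dt = meta$bin_dt,
                 n_particles = meta$n_particles, params = meta$truth),
            class = "fcs_trace")
}
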