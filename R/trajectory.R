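#' Construct a single-vesicle trajectory
#'
#' A `vesicle_trajectory` is a data frame with columns `time`, `donor` and
#' `acceptor` (counts per frame), plus the frame interval, optional injection
#' time and an identifier carried as attributes.
#'
#' @param time Time from acquisition start (s), strictly increasing.
#' @param donor,acceptor Per-frame counts, same length as `time`.
#' @param frame_dt Frame interval (s).
#' @param t0 Injection time (s) or `NULL` when unknown.
#' @param vesicle_id Identifier string.
#' @param truth Optional list of generating parameters (synthetic data only).
#' @return An object of class `vesicle_trajectory` (also a data frame).
#' @export
vesicle_trajectory <- function(time, donor, acceptor, frame_dt,
                               t0 = NULL, vesicle_id = "v1", truth = NULL) {
  if (length(donor) != length(time) || length(acceptor) != length(time)) {
    stop_invalid("channel and time vectors must have equal length")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop_invalid("`time` must be strictly increasing")
  }
  check_positive(frame_dt, "frame_dt")
  structure(
    data.frame(time = time, donor = donor, acceptor = acceptor),
    frame_dt = frame_dt, t0 = t0, vesicle_id = vesicle_id, truth = truth,
    class = c("vesicle_trajectory", "data.frame")
  )
}

#' @export
print.vesicle_trajectory <- function(x, ...) {
  cat(sprintf(
    "<vesicle_trajectory '%s'> %d frames, dt = %g s%s\n",
    attr(x, "vesicle_id"), nrow(x), attr(x, "frame_dt"),
    if (!is.null(attr(x, "t0"))) sprintf(", injection at %g s", attr(x, "t0")) else ""
  ))
  print(utils::head(as.data.frame(x), 3))
  invisible(x)
}

# Noise-free expected donor/acceptor signals of the forward model, without
# background. Returns list(E, I_tot, donor, acceptor) at times `t`.
solub_expectation <- function(params, t) {
  p <- params
  s <- pmax(t - p$t0, 0)
  after <- t >= p$t0
  E <- ifelse(after,
              p$E_plateau + (p$E0 - p$E_plateau) * 2^(-s / p$t_E),
              p$E0)
  I_tot <- ifelse(after,
                  p$I_tot0 * (1 - p$f_loss * (1 - 2^(-s / p$t_L))),
                  p$I_tot0)
  if (p$bleach_rate > 0) I_tot <- I_tot * exp(-p$bleach_rate * t)
  list(E = E, I_tot = I_tot,
       donor = (1 - E) * I_tot, acceptor = E * I_tot)
}

#' Generate a synthetic single-vesicle FRET trajectory
#'
#' Simulates the forward solubilization mechanism: before the injection at
#' `t0` the FRET efficiency sits at `E0` and total intensity at `I_tot0`;
#' afterwards the efficiency decays to `E_plateau` with half-life `t_E`
#' (swelling) while the total intensity loses a fraction `f_loss` with
#' half-life `t_L` (lysis). Expected donor and acceptor signals are
#' `(1 - E) * I_tot` and `E * I_tot`; with `noise = TRUE` each frame is an
#' independent Poisson draw about its expectation plus background.
#'
#' @param params A [solub_params()] object.
#' @param seed Integer seed; identical `params` + `seed` give identical output.
#' @param noise Apply Poisson shot noise (`TRUE`, default) or return the
#'   noise-free expectation (`FALSE`; `seed` may then be `NULL`).
#' @param vesicle_id Identifier stored on the trajectory.
#' @return A [vesicle_trajectory()] with the generating parameters attached as
#'   the `truth` attribute.
#' @export
generate_trajectory <- function(params, seed = NULL, noise = TRUE,
                                vesicle_id = "v1") {
  stopifnot(inherits(params, "solub_params"))
  t <- seq(params$frame_dt, params$duration, by = params$frame_dt)
  mu <- solub_expectation(params, t)
  d_mean <- mu$donor + params$background
  a_mean <- mu$acceptor + params$background
  if (any(d_mean < 0) || any(a_mean < 0)) {
    stop_invalid("model expectation produced negative intensities")
  }
  if (noise) {
    if (is.null(seed)) stop_invalid("`seed` is required when `noise = TRUE`")
    ch <- with_seed(seed, {
      list(d = rpois(length(t), d_mean), a = rpois(length(t), a_mean))
    })
  } else {
    ch <- list(d = d_mean, a = a_mean)
  }
  vesicle_trajectory(t, ch$d, ch$a, frame_dt = params$frame_dt,
                     t0 = params$t0, vesicle_id = vesicle_id,
                     truth = unclass(params))
}

#' Write / read a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV holds columns `time_s`, `donor`, `acceptor`; the sidecar
#' (`<path>.json`) records `frame_dt`, `t0`, `vesicle_id` and, for synthetic
#' data, the generating truth parameters.
#'
#' @param traj A [vesicle_trajectory()].
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a [vesicle_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "vesicle_trajectory"))
  df <- data.frame(time_s = traj$time, donor = traj$donor,
                   acceptor = traj$acceptor)
  write.csv(df, path, row.names = FALSE)
  meta <- list(frame_dt = attr(traj, "frame_dt"), t0 = attr(traj, "t0"),
               vesicle_id = attr(traj, "vesicle_id"),
               truth = attr(traj, "truth"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  vesicle_trajectory(df$time_s, df$donor, df$acceptor,
                     frame_dt = meta$frame_dt %||% diff(df$time_s[1:2]),
                     t0 = meta$t0,
                     vesicle_id = meta$vesicle_id %||% basename(path),
                     truth = meta$truth)
}
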