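#' Render dual-channel image stacks from vesicle trajectories
#'
#' Each vesicle is a fixed 2D Gaussian spot (surface-immobilized, so no
#' tracking is needed) whose discretely integrated intensity per frame equals
#' the trajectory value exactly; the donor and acceptor channels share the
#' spot geometry. Per-pixel Poisson noise is applied over signal plus
#' background.
#'
#' Coordinates are 0-based `(row, col)` with pixel centers at integer
#' positions.
#'
#' @param trajectories List of [vesicle_trajectory()] objects with identical
#'   time bases.
#' @param positions Matrix (n x 2) of 0-based `(row, col)` spot centers, one
#'   per trajectory; must lie within the frame. Spots closer than
#'   `4 * psf_sigma` trigger an overlap warning.
#' @param psf_sigma Gaussian PSF standard deviation (pixels).
#' @param frame_shape `c(rows, cols)` of each frame.
#' @param background Mean background per pixel (counts/frame).
#' @param seed Integer seed (required when `noise = TRUE`).
#' @param noise Apply per-pixel Poisson noise.
#' @return An `image_stack`: list with 3D arrays `donor`, `acceptor`
#'   (rows x cols x frames), `frame_dt`, `positions`, `psf_sigma`,
#'   `background` and `truth` (the input trajectories' truth attributes).
#' @export
generate_image_stack <- function(trajectories, positions, psf_sigma = 1.5,
                                 frame_shape = c(64, 64), background = 2,
                                 seed = NULL, noise = TRUE) {
  if (inherits(trajectories, "vesicle_trajectory")) trajectories <- list(trajectories)
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (nrow(positions) != length(trajectories)) {
    stop_invalid("need one position per trajectory")
  }
  nr <- frame_shape[1]; nc <- frame_shape[2]
  if (any(positions[, 1] < 0 | positions[, 1] > nr - 1 |
          positions[, 2] < 0 | positions[, 2] > nc - 1)) {
    stop_invalid("spot positions must lie within the frame")
  }
  if (nrow(positions) > 1) {
    dmin <- min(dist(positions))
    if (dmin < 4 * psf_sigma) {
      warning(sprintf("spots overlap: minimum separation %.2f px < 4 sigma", dmin),
              call. = FALSE)
    }
  }
  nt <- nrow(trajectories[[1]])
  if (!all(vapply(trajectories, nrow, integer(1)) == nt)) {
    stop_invalid("trajectories must share a common time base")
  }
  frame_dt <- attr(trajectories[[1]], "frame_dt")

  render_channel <- function(channel) {
    acc <- matrix(0, nr * nc, nt)
    R <- ceiling(5 * psf_sigma)
    for (i in seq_along(trajectories)) {
      r0 <- positions[i, 1]; c0 <- positions[i, 2]
      rows <- max(0, floor(r0) - R):min(nr - 1, ceiling(r0) + R)
      cols <- max(0, floor(c0) - R):min(nc - 1, ceiling(c0) + R)
      grid <- expand.grid(r = rows, cl = cols)
      w <- exp(-((grid$r - r0)^2 + (grid$cl - c0)^2) / (2 * psf_sigma^2))
      w <- w / sum(w)  # discrete mass = 1 so the spot integrates to the trace
      lin <- grid$cl * nr + grid$r + 1L
      vals <- trajectories[[i]][[channel]]
      acc[lin, ] <- acc[lin, ] + tcrossprod(w, vals)
    }
    acc + background
  }
  d <- render_channel("donor")
  a <- render_channel("acceptor")
  if (noise) {
    if (is.null(seed)) stop_invalid("`seed` is required when `noise = TRUE`")
    with_seed(seed, {
      d[] <- rpois(length(d), d)
      a[] <- rpois(length(a), a)
    })
  }
  structure(
    list(donor = array(d, c(nr, nc, nt)), acceptor = array(a, c(nr, nc, nt)),
         frame_dt = frame_dt, positions = positions, psf_sigma = psf_sigma,
         background = background,
         truth = lapply(trajectories, attr, "truth")),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf("<image_stack> %d x %d px, %d frames, %d spot(s), dt = %g s\n",
              d[1], d[2], d[3], nrow(x$positions), x$frame_dt))
  invisible(x)
}

#' Time-averaged image of one channel
#'
#' Averaging the stable pre-injection frames maximizes detection SNR for
#' immobilized vesicles.
#'
#' @param stack An `image_stack`.
#' @param channel `"donor"` or `"acceptor"`.
#' @param frames Frame indices to average; default all frames before the
#'   first trajectory's injection time, falling back to the first 10.
#' @return Numeric matrix.
#' @export
average_image <- function(stack, channel = "donor", frames = NULL) {
  arr <- stack[[channel]]
  if (is.null(frames)) {
    t0 <- stack$truth[[1]]$t0
    frames <- if (!is.null(t0)) {
      which(seq_len(dim(arr)[3]) * stack$frame_dt < t0)
    } else {
      integer(0)
    }
    if (length(frames) < 1) frames <- seq_len(min(10, dim(arr)[3]))
  }
  apply(arr[, , frames, drop = FALSE], c(1, 2), mean)
}
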