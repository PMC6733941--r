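#' Apparent FRET efficiency
#'
#' Computes `E = I_A / (I_A + gamma * I_D)`. Because the donor and acceptor
#' dyes used here (DiI/DiD) have similar quantum yields, the apparent
#' efficiency closely matches the true transfer efficiency and `gamma`
#' defaults to 1. Negative (over-corrected) intensities are clipped to zero
#' with a warning; samples with non-positive total intensity yield `NA`
#' rather than an error so trajectories keep their time base.
#'
#' @param I_D,I_A Donor and acceptor intensities (counts), vectorized.
#' @param gamma Detection-efficiency correction factor (default 1).
#' @return Numeric vector of efficiencies in `[0, 1]`, `NA` where undefined.
#' @examples
#' apparent_fret(50, 50)   # 0.5
#' apparent_fret(78, 22)   # 0.22
#' @export
apparent_fret <- function(I_D, I_A, gamma = 1) {
  check_positive(gamma, "gamma")
  if (any(I_D < 0, na.rm = TRUE) || any(I_A < 0, na.rm = TRUE)) {
    warning("negative intensities clipped to 0", call. = FALSE)
    I_D <- pmax(I_D, 0)
    I_A <- pmax(I_A, 0)
  }
  tot <- I_A + gamma * I_D
  E <- ifelse(tot > 0, I_A / tot, NA_real_)
  E
}

#' FRET efficiency trace of a trajectory
#'
#' @param traj A [vesicle_trajectory()].
#' @param gamma Correction factor passed to [apparent_fret()].
#' @return Numeric vector, one efficiency per frame.
#' @export
fret_trace <- function(traj, gamma = 1) {
  apparent_fret(traj$donor, traj$acceptor, gamma = gamma)
}

#' Inter-dye distance from FRET efficiency
#'
#' Inverts `E = R0^6 / (R0^6 + R^6)` to `R = R0 * ((1 - E) / E)^(1/6)`.
#' `R0` is the Foerster radius of the dye pair; it is not measured by this
#' package and defaults to the literature DiI/DiD value of 5.3 nm.
#'
#' @param E FRET efficiency, strictly inside (0, 1); vectorized.
#' @param R0 Foerster radius (nm).
#' @return A data frame with columns `R` (nm), `R0` and `ratio = R/R0`.
#' @examples
#' distance_from_fret(0.5, 5.3)$R    # equals R0
#' distance_from_fret(0.22, 5.3)$R   # ~6.5 nm
#' @export
distance_from_fret <- function(E, R0 = 5.3) {
  check_positive(R0, "R0")
  if (any(E <= 0 | E >= 1)) {
    stop_invalid("`E` must lie strictly inside (0, 1); E = 0 or 1 maps to an infinite or zero distance")
  }
  R <- R0 * ((1 - E) / E)^(1 / 6)
  data.frame(R = R, R0 = R0, ratio = R / R0)
}

#' FRET efficiency from inter-dye distance
#'
#' `E = R0^6 / (R0^6 + R^6)`; exact inverse of [distance_from_fret()].
#'
#' @param R Inter-dye distance (nm), positive; vectorized.
#' @param R0 Foerster radius (nm).
#' @return Numeric efficiency vector.
#' @export
fret_from_distance <- function(R, R0 = 5.3) {
  check_positive(R0, "R0")
  if (any(R < 0)) stop_invalid("`R` must be non-negative")
  r6 <- (R / R0)^6
  1 / (1 + r6)
}

#' Background correction
#'
#' Subtracts a per-channel background from a trajectory (constant mode) or
#' estimates the background of an image as the median over a designated
#' background region (region mode). The value used is recorded in the
#' `background` attribute of the result.
#'
#' @param x A [vesicle_trajectory()] or a numeric matrix (single image).
#' @param ... Passed to methods.
#' @return Same class as `x`, background-subtracted.
#' @export
correct_background <- function(x, ...) UseMethod("correct_background")

#' @rdname correct_background
#' @param donor,acceptor Constant background per channel (counts/frame).
#' @export
correct_background.vesicle_trajectory <- function(x, donor = 0, acceptor = 0, ...) {
  check_nonneg(donor, "donor")
  check_nonneg(acceptor, "acceptor")
  out <- x
  out$donor <- x$donor - donor
  out$acceptor <- x$acceptor - acceptor
  attr(out, "background") <- c(donor = donor, acceptor = acceptor)
  out
}

#' @rdname correct_background
#' @param region Two-column matrix of (row, col) pixel indices (1-based)
#'   designating the background region of the image.
#' @export
correct_background.matrix <- function(x, region, ...) {
  if (missing(region) || NROW(region) == 0) {
    stop_invalid("`region` must designate at least one background pixel")
  }
  region <- as.matrix(region)
  bg <- median(x[region])
  out <- x - bg
  attr(out, "background") <- bg
  out
}

#' Median background level of an image region
#'
#' @param image Numeric matrix.
#' @param region Two-column matrix of (row, col) indices (1-based).
#' @return Median pixel value over the region.
#' @export
estimate_background <- function(image, region) {
  if (NROW(region) == 0) stop_invalid("empty background region")
  median(image[as.matrix(region)])
}
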