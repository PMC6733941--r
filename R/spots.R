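# Spot detection, channel pairing and aperture photometry.
# Coordinates throughout are 0-based (row, col) with pixel centers at
# integer positions; sub-pixel centers come from intensity-weighted
# centroids.

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge renormalization, via smoothing matrices.
gaussian_blur <- function(image, sigma) {
  smooth_mat <- function(n) {
    k <- gaussian_kernel_1d(sigma)
    r <- (length(k) - 1) / 2
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- k[j - i + r + 1]
      S[i, j] <- w / sum(w)
    }
    S
  }
  smooth_mat(nrow(image)) %*% image %*% t(smooth_mat(ncol(image)))
}

#' Detect diffraction-limited spots in a single image
#'
#' Gaussian-smooths the image, finds local maxima above
#' `median + threshold_factor * MAD` of the smoothed image, refines each
#' center by an intensity-weighted centroid in a
#' `(2 ceil(2 sigma) + 1)^2` window on the background-subtracted image, and
#' enforces a minimum pairwise separation by keeping the brighter spot.
#'
#' @param image Numeric matrix (typically the time-averaged pre-injection
#'   donor image, see [average_image()]).
#' @param sigma Approximate PSF standard deviation (pixels).
#' @param threshold_factor Detection threshold in MADs above the median.
#' @param min_separation Minimum allowed center distance (pixels).
#' @return A `spot_set` data frame: `row`, `col` (0-based, sub-pixel),
#'   `score` (peak height in MADs). A blank image yields zero rows.
#' @export
detect_spots <- function(image, sigma = 1.5, threshold_factor = 5,
                         min_separation = 4 * sigma) {
  stopifnot(is.matrix(image))
  sm <- gaussian_blur(image, sigma)
  med <- median(sm)
  scale <- mad(sm)
  # numerically flat image: nothing to detect (guards fp wobble from the blur)
  if (diff(range(sm)) <= 1e-9 * max(abs(sm), 1)) {
    return(structure(data.frame(row = numeric(0), col = numeric(0),
                                score = numeric(0)),
                     class = c("spot_set", "data.frame")))
  }
  thr <- med + threshold_factor * scale
  nr <- nrow(sm); nc <- ncol(sm)
  # strict local maxima over the 8-neighborhood, away from the 1-px border
  is_max <- matrix(FALSE, nr, nc)
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  nb_ok <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_ok <- nb_ok & (ctr >= sm[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  is_max[2:(nr - 1), 2:(nc - 1)] <- nb_ok
  peaks <- which(is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0) {
    return(structure(data.frame(row = numeric(0), col = numeric(0),
                                score = numeric(0)),
                     class = c("spot_set", "data.frame")))
  }
  bg <- median(image)
  w <- ceiling(2 * sigma)
  refine <- function(pr, pc) {
    rows <- max(1, pr - w):min(nr, pr + w)
    cols <- max(1, pc - w):min(nc, pc + w)
    patch <- pmax(image[rows, cols, drop = FALSE] - bg, 0)
    tot <- sum(patch)
    if (tot <= 0) return(c(pr - 1, pc - 1))
    c(sum(rowSums(patch) * (rows - 1)) / tot,
      sum(colSums(patch) * (cols - 1)) / tot)
  }
  centers <- t(apply(peaks, 1, function(p) refine(p[1], p[2])))
  score <- (sm[peaks] - med) / max(scale, .Machine$double.eps)
  ord <- order(score, decreasing = TRUE)
  keep <- logical(length(ord))
  for (i in ord) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt((centers[keep, 1] - centers[i, 1])^2 +
                (centers[keep, 2] - centers[i, 2])^2)
    if (all(d >= min_separation)) keep[i] <- TRUE
  }
  structure(
    data.frame(row = centers[keep, 1], col = centers[keep, 2],
               score = score[keep]),
    class = c("spot_set", "data.frame")
  )
}

#' Pair donor- and acceptor-channel spots
#'
#' Maps acceptor spots into the donor frame with a known geometric transform
#' (a pure translation for the synthetic relay optics) and greedily matches
#' nearest neighbors within `tolerance_px`; unmatched spots on either side
#' are reported separately.
#'
#' @param donor_spots,acceptor_spots `spot_set` data frames.
#' @param transform Donor-to-acceptor translation `(drow, dcol)`.
#' @param tolerance_px Maximum residual distance for a match (pixels).
#' @return A `channel_pairing`: `pairs` (data frame with donor and acceptor
#'   coordinates plus `residual_px`), `unmatched_donor`, `unmatched_acceptor`
#'   (row indices into the inputs).
#' @export
pair_channels <- function(donor_spots, acceptor_spots, transform = c(0, 0),
                          tolerance_px = 2) {
  a_mapped <- cbind(acceptor_spots$row - transform[1],
                    acceptor_spots$col - transform[2])
  nd <- nrow(donor_spots); na <- nrow(acceptor_spots)
  pairs <- data.frame(donor_idx = integer(0), acceptor_idx = integer(0),
                      donor_row = numeric(0), donor_col = numeric(0),
                      acceptor_row = numeric(0), acceptor_col = numeric(0),
                      residual_px = numeric(0))
  if (nd > 0 && na > 0) {
    D <- sqrt(outer(donor_spots$row, a_mapped[, 1], "-")^2 +
                outer(donor_spots$col, a_mapped[, 2], "-")^2)
    repeat {
      m <- which.min(D)
      if (!length(m) || !is.finite(D[m]) || D[m] > tolerance_px) break
      i <- (m - 1) %% nd + 1
      j <- (m - 1) %/% nd + 1
      pairs <- rbind(pairs, data.frame(
        donor_idx = i, acceptor_idx = j,
        donor_row = donor_spots$row[i], donor_col = donor_spots$col[i],
        acceptor_row = acceptor_spots$row[j], acceptor_col = acceptor_spots$col[j],
        residual_px = D[m]))
      D[i, ] <- Inf
      D[, j] <- Inf
    }
  }
  structure(
    list(pairs = pairs,
         unmatched_donor = setdiff(seq_len(nd), pairs$donor_idx),
         unmatched_acceptor = setdiff(seq_len(na), pairs$acceptor_idx)),
    class = "channel_pairing"
  )
}

circular_mask_idx <- function(center, radius, nr, nc) {
  r0 <- center[1]; c0 <- center[2]  # 0-based
  rows <- max(0, floor(r0 - radius)):min(nr - 1, ceiling(r0 + radius))
  cols <- max(0, floor(c0 - radius)):min(nc - 1, ceiling(c0 + radius))
  grid <- expand.grid(r = rows, cl = cols)
  d2 <- (grid$r - r0)^2 + (grid$cl - c0)^2
  sel <- d2 <= radius^2
  list(lin = grid$cl[sel] * nr + grid$r[sel] + 1L, n = sum(sel),
       clipped = (r0 - radius < 0 || r0 + radius > nr - 1 ||
                    c0 - radius < 0 || c0 + radius > nc - 1))
}

#' Aperture photometry of one vesicle across a dual-channel stack
#'
#' Per frame and channel, sums pixels within `aperture_radius` of the fixed
#' spot center and subtracts the annulus-median background scaled to the
#' aperture area.
#'
#' @param stack_donor,stack_acceptor 3D arrays (rows x cols x frames) or an
#'   `image_stack` passed as `stack_donor` (then `stack_acceptor` is taken
#'   from it).
#' @param pair One row of a [pair_channels()] `pairs` data frame (or any list
#'   with `donor_row`, `donor_col`, `acceptor_row`, `acceptor_col`).
#' @param aperture_radius Aperture radius (pixels).
#' @param annulus Inner and outer radii of the background annulus (pixels).
#' @param frame_dt Frame interval (s).
#' @param t0 Injection time passed through to the trajectory.
#' @param vesicle_id Identifier.
#' @return A [vesicle_trajectory()]; attribute `edge_clipped` is `TRUE` when
#'   either aperture was clipped by the image edge.
#' @export
extract_trace <- function(stack_donor, stack_acceptor = NULL, pair,
                          aperture_radius = 4,
                          annulus = c(aperture_radius + 2, aperture_radius + 5),
                          frame_dt = NULL, t0 = NULL, vesicle_id = "v1") {
  if (inherits(stack_donor, "image_stack")) {
    frame_dt <- frame_dt %||% stack_donor$frame_dt
    stack_acceptor <- stack_donor$acceptor
    stack_donor <- stack_donor$donor
  }
  if (is.null(frame_dt)) stop_invalid("`frame_dt` is required")
  one_channel <- function(arr, center) {
    nr <- dim(arr)[1]; nc <- dim(arr)[2]; nt <- dim(arr)[3]
    ap <- circular_mask_idx(center, aperture_radius, nr, nc)
    an_out <- circular_mask_idx(center, annulus[2], nr, nc)
    an_in <- circular_mask_idx(center, annulus[1], nr, nc)
    an_lin <- setdiff(an_out$lin, an_in$lin)
    if (!length(an_lin)) stop_invalid("empty background annulus")
    m <- matrix(arr, nr * nc, nt)
    ap_sum <- colSums(m[ap$lin, , drop = FALSE])
    bg <- apply(m[an_lin, , drop = FALSE], 2, median)
    list(trace = ap_sum - bg * ap$n, clipped = ap$clipped)
  }
  d <- one_channel(stack_donor, c(pair$donor_row, pair$donor_col))
  a <- one_channel(stack_acceptor, c(pair$acceptor_row, pair$acceptor_col))
  clipped <- d$clipped || a$clipped
  if (clipped) {
    warning("aperture clipped by image edge; trajectory flagged", call. = FALSE)
  }
  out <- vesicle_trajectory(seq_along(d$trace) * frame_dt, d$trace, a$trace,
                            frame_dt = frame_dt, t0 = t0,
                            vesicle_id = vesicle_id)
  attr(out, "edge_clipped") <- clipped
  out
}

#' Extract all paired vesicle trajectories from an image stack
#'
#' Convenience wrapper: detection on the time-averaged pre-injection donor
#' image, pairing against the acceptor average, then [extract_trace()] per
#' pair.
#'
#' @param stack An `image_stack`.
#' @param sigma,threshold_factor Passed to [detect_spots()].
#' @param transform,tolerance_px Passed to [pair_channels()].
#' @param aperture_radius,annulus Passed to [extract_trace()].
#' @param t0 Injection time recorded on the trajectories.
#' @return List of [vesicle_trajectory()] objects.
#' @export
extract_all_traces <- function(stack, sigma = stack$psf_sigma %||% 1.5,
                               threshold_factor = 5, transform = c(0, 0),
                               tolerance_px = 2, aperture_radius = 4 * sigma,
                               annulus = c(aperture_radius + 2, aperture_radius + 5),
                               t0 = NULL) {
  dspots <- detect_spots(average_image(stack, "donor"), sigma, threshold_factor)
  aspots <- detect_spots(average_image(stack, "acceptor"), sigma, threshold_factor)
  pairing <- pair_channels(dspots, aspots, transform, tolerance_px)
  lapply(seq_len(nrow(pairing$pairs)), function(i) {
    extract_trace(stack, pair = pairing$pairs[i, ],
                  aperture_radius = aperture_radius, annulus = annulus,
                  t0 = t0 %||% stack$truth[[1]]$t0,
                  vesicle_id = sprintf("v%03d", i))
  })
}
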