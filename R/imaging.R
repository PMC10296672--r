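# Per-frame dielectric-contrast imaging: baseline estimation, adjoint
# (matched-filter) backprojection of the channel residual onto a polar pixel
# grid, per-frame aggregation, and the concatenated longitudinal contrast map
# (a B-scan: frames along one axis, angle along the other).

#' Polar reconstruction grid
#'
#' Pixels at radial bin centres over the annulus \code{(r_min, r_max]} and
#' angular bin centres over \code{[0, 2*pi)}. The annulus starts just
#' outside the accessory surface (ring radius plus a small standoff):
#' tissue cannot occupy the volume the device itself fills, and pixels
#' inside the ring only host a mirror lobe of the adjoint point-spread
#' function that degrades angular localisation. \code{r_max} exceeds the
#' ring radius so the wall behind the antennas is imaged. Pixels closer
#' than \code{antenna_clearance} to any antenna are excluded (set to zero)
#' during reconstruction; with the default annulus no pixel comes that
#' close, the guard matters only for custom grids reaching the ring.
#'
#' @param n_r number of radial bins (default 20).
#' @param r_min inner radius in mm (default 10.5: the 10 mm ring radius
#'   plus a 0.5 mm standoff for the device shell).
#' @param r_max outer radius in mm (default 25).
#' @param n_theta number of angular bins (default 64; keep divisible by the
#'   antenna count so array symmetries map onto whole bins).
#' @param antenna_clearance exclusion radius around each antenna, mm
#'   (default 0.5).
#' @return an object of class \code{mw_grid}.
#' @export
polar_grid <- function(n_r = 20L, r_min = 10.5, r_max = 25, n_theta = 64L,
                       antenna_clearance = 0.5) {
  stopifnot(n_r >= 1, n_theta >= 1, r_min >= 0, r_max > r_min,
            antenna_clearance >= 0)
  structure(list(
    n_r = as.integer(n_r), r_min = r_min, r_max = r_max,
    n_theta = as.integer(n_theta),
    antenna_clearance = antenna_clearance,
    r_centers = r_min + (seq_len(n_r) - 0.5) * (r_max - r_min) / n_r,
    theta_centers = (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  ), class = "mw_grid")
}

#' @export
print.mw_grid <- function(x, ...) {
  cat(sprintf("<mw_grid> %d x %d polar pixels over (%g, %g] mm\n",
              x$n_r, x$n_theta, x$r_min, x$r_max))
  invisible(x)
}

# pixel index = (theta_bin - 1) * n_r + r_bin (radius fastest)
grid_pixels <- function(grid) {
  r <- rep(grid$r_centers, times = grid$n_theta)
  th <- rep(grid$theta_centers, each = grid$n_r)
  cbind(x = r * cos(th), y = r * sin(th))
}

# Adjoint weight matrix W[pair, pixel] = G(tx, p) * G(p, rx); excluded
# pixels (inside the antenna clearance) get weight 0.
reconstruct_weights <- function(geometry, schedule, grid, k) {
  px <- grid_pixels(grid)
  npix <- nrow(px)
  ants <- rbind(geometry$tx_pos, geometry$rx_pos)
  dmin <- rep(Inf, npix)
  for (a in seq_len(nrow(ants))) {
    dmin <- pmin(dmin, sqrt((px[, 1] - ants[a, 1])^2 +
                            (px[, 2] - ants[a, 2])^2))
  }
  keep <- dmin > grid$antenna_clearance
  # antenna-to-pixel propagation, shared across pairs
  gtx <- matrix(0i, geometry$n_tx, npix)
  grx <- matrix(0i, geometry$n_rx, npix)
  for (a in seq_len(geometry$n_tx)) {
    d <- sqrt((px[keep, 1] - geometry$tx_pos[a, 1])^2 +
              (px[keep, 2] - geometry$tx_pos[a, 2])^2)
    gtx[a, keep] <- greens_dist(d, k)
  }
  for (a in seq_len(geometry$n_rx)) {
    d <- sqrt((px[keep, 1] - geometry$rx_pos[a, 1])^2 +
              (px[keep, 2] - geometry$rx_pos[a, 2])^2)
    grx[a, keep] <- greens_dist(d, k)
  }
  gtx[schedule$tx, , drop = FALSE] * grx[schedule$rx, , drop = FALSE]
}

#' Estimate the per-channel baseline from a leading stream window
#'
#' Component-wise median (real and imaginary parts separately) over the first
#' \code{window} frames. The window is assumed to cover healthy,
#' contact-free colon -- an operator responsibility mirrored by the
#' calibration step of the detector. The median keeps the estimate usable
#' when a minority of window frames are corrupted.
#'
#' @param stream an \code{mw_stream}.
#' @param window number of leading frames (default 50).
#' @return complex vector, one estimate per channel.
#' @export
estimate_baseline <- function(stream, window = 50L) {
  stopifnot(inherits(stream, "mw_stream"), window >= 1)
  if (window > nrow(stream$channels)) {
    stop("baseline window exceeds the stream length")
  }
  head_ch <- stream$channels[seq_len(window), , drop = FALSE]
  complex(real = apply(Re(head_ch), 2, stats::median),
          imaginary = apply(Im(head_ch), 2, stats::median))
}

#' Reconstruct the contrast image of one frame
#'
#' Adjoint backprojection of the channel residual \eqn{d = data - baseline}:
#' \deqn{I(p) = | \sum_{pairs} \overline{G(tx, p) G(p, rx)} \, d_{pair} |}
#' Pixels inside the antenna clearance are set to zero. The image is a
#' qualitative contrast-magnitude map: homogeneous (healthy) frames
#' reconstruct to zero, a lesion appears as a bright blob near its true
#' position.
#'
#' @param frame an \code{mw_frame} or a complex channel vector.
#' @param baseline complex per-channel baseline (length = schedule rows).
#' @param geometry,schedule,grid acquisition geometry, schedule and
#'   reconstruction grid.
#' @param k complex background wavenumber (rad/m).
#' @return an object of class \code{mw_image}: an \code{n_r x n_theta}
#'   non-negative matrix with the grid attached.
#' @export
reconstruct_frame <- function(frame, baseline, geometry, schedule, grid, k) {
  data <- if (inherits(frame, "mw_frame")) frame$data else as.complex(frame)
  if (length(baseline) != nrow(schedule)) {
    stop("baseline length does not match the schedule")
  }
  w <- reconstruct_weights(geometry, schedule, grid, k)
  v <- abs(as.vector(crossprod(Conj(w), data - baseline)))
  img <- matrix(v, grid$n_r, grid$n_theta)
  structure(img, class = c("mw_image", class(img)), grid = grid,
            frame_idx = if (inherits(frame, "mw_frame")) frame$frame_idx else NA_integer_)
}

#' Aggregate a frame image to an angular profile and a scalar
#'
#' The angular profile takes the maximum over radius within each angular
#' bin; the scalar aggregate is the maximum of the profile. A peak statistic
#' is used (not a mean) because lesion evidence is a localised bright spot.
#'
#' @param image an \code{mw_image}.
#' @return list with \code{profile} (length n_theta) and \code{aggregate}
#'   (scalar).
#' @export
aggregate_frame <- function(image) {
  stopifnot(inherits(image, "mw_image"))
  profile <- apply(unclass(image), 2, max)
  list(profile = profile, aggregate = max(profile))
}

#' Build the concatenated contrast map of a stream
#'
#' Reconstructs and aggregates every frame, stacking the angular profiles
#' into an \code{n_frames x n_theta} B-scan. Bright wide runs along the
#' frame axis indicate polyps; bright short runs, stool remnants.
#'
#' @param stream an \code{mw_stream}.
#' @param baseline complex per-channel baseline (e.g. from
#'   \code{\link{estimate_baseline}}).
#' @param grid a \code{\link{polar_grid}}.
#' @return an object of class \code{mw_contrast_map}: \code{profiles}
#'   (n_frames x n_theta), \code{aggregate} (n_frames), \code{grid}.
#' @export
build_contrast_map <- function(stream, baseline, grid = polar_grid()) {
  stopifnot(inherits(stream, "mw_stream"))
  w <- reconstruct_weights(stream$geometry, stream$schedule, grid,
                           stream$k_bg)
  resid <- sweep(stream$channels, 2, baseline, "-")
  pix <- abs(resid %*% Conj(w)) # n_frames x n_pixels
  n_r <- grid$n_r
  profiles <- matrix(0, nrow(pix), grid$n_theta)
  for (l in seq_len(grid$n_theta)) {
    block <- pix[, ((l - 1L) * n_r + 1L):(l * n_r), drop = FALSE]
    profiles[, l] <- do.call(pmax, as.data.frame(block))
  }
  structure(list(profiles = profiles,
                 aggregate = apply(profiles, 1, max), grid = grid),
            class = "mw_contrast_map")
}

#' @export
print.mw_contrast_map <- function(x, ...) {
  cat(sprintf(
    "<mw_contrast_map> %d frames x %d angular bins, peak aggregate %.3g\n",
    nrow(x$profiles), ncol(x$profiles), max(x$aggregate)))
  invisible(x)
}

#' Heatmap of a contrast map
#'
#' Frames on the x axis, angular bins on the y axis, brightness = contrast
#' magnitude: the longitudinal B-scan on which wide bright runs are polyps.
#'
#' @param x an \code{mw_contrast_map}.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.mw_contrast_map <- function(x, ...) {
  graphics::image(
    x = seq_len(nrow(x$profiles)) - 1L, y = x$grid$theta_centers,
    z = x$profiles, xlab = "frame", ylab = "angle (rad)",
    col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...)
  invisible(x)
}
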