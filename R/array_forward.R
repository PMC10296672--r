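# The antenna ring, its switching schedule, and the Born-approximation
# forward model. Each frame is treated as an independent 2D cross-section:
# cylindrical waves propagate in a homogeneous lossy background (the mucosa
# tissue class) and each scatterer contributes a single-scattering term
# amplitude * chi * G(tx, s) * G(s, rx) on top of the deterministic direct
# tx->rx coupling baseline.

#' Antenna ring geometry
#'
#' Eight transmitting and eight receiving antennas on a ring matching the
#' 20 mm accessory diameter. The receive ring is co-indexed with the transmit
#' ring but rotated half an antenna pitch, so each receiver sits between two
#' transmitters: receiver \code{i} is the one adjacent to transmitter
#' \code{i}, receivers \code{i-1} and \code{i+1} its closest diagonals.
#'
#' @param n_antennas antennas per ring (default 8).
#' @param ring_radius ring radius in mm (default 10).
#' @param frequency working frequency in Hz (default 7.5e9).
#' @param rx_offset angular offset of the receive ring, radians (default half
#'   a pitch, \code{pi / n_antennas}).
#' @return an object of class \code{mw_geometry} with antenna angles and
#'   cartesian positions (mm).
#' @export
array_geometry <- function(n_antennas = 8L, ring_radius = 10,
                           frequency = 7.5e9,
                           rx_offset = pi / n_antennas) {
  stopifnot(n_antennas >= 3, ring_radius > 0, frequency > 0)
  tx_angles <- 2 * pi * (seq_len(n_antennas) - 1L) / n_antennas
  rx_angles <- (tx_angles + rx_offset) %% (2 * pi)
  structure(list(
    n_tx = as.integer(n_antennas), n_rx = as.integer(n_antennas),
    ring_radius = ring_radius, frequency = frequency,
    tx_angles = tx_angles, rx_angles = rx_angles,
    tx_pos = ring_radius * cbind(cos(tx_angles), sin(tx_angles)),
    rx_pos = ring_radius * cbind(cos(rx_angles), sin(rx_angles))
  ), class = "mw_geometry")
}

#' @export
print.mw_geometry <- function(x, ...) {
  cat(sprintf("<mw_geometry> %d+%d antennas, ring radius %g mm, %g GHz\n",
              x$n_tx, x$n_rx, x$ring_radius, x$frequency / 1e9))
  invisible(x)
}

# tx/rx index pairs for an n-antenna ring: per transmitter the adjacent
# receiver (same index) then the two diagonals (index -1, +1, modular)
schedule_pairs <- function(n_antennas = 8L) {
  tx <- rep(seq_len(n_antennas), each = 3L)
  off <- rep(c(0L, -1L, 1L), times = n_antennas)
  rx <- ((tx - 1L + off) %% n_antennas) + 1L
  data.frame(tx = tx, rx = rx)
}

#' Switching schedule of the multistatic acquisition
#'
#' For each transmitter in turn, the total field is recorded at the adjacent
#' receiver and the two closest diagonal receivers: 3 pairs per transmitter,
#' 24 channels per frame for the default 8+8 ring.
#'
#' @param geometry an \code{\link{array_geometry}}.
#' @return data frame of class \code{mw_schedule} with 1-based columns
#'   \code{tx}, \code{rx} in acquisition order.
#' @export
build_schedule <- function(geometry) {
  stopifnot(inherits(geometry, "mw_geometry"))
  sched <- schedule_pairs(geometry$n_tx)
  class(sched) <- c("mw_schedule", "data.frame")
  sched
}

#' 2D outgoing-wave Green's function
#'
#' \eqn{G(r) = (-j/4) H_0^{(2)}(k r)} between two points in the homogeneous
#' background, with \eqn{r} the Euclidean distance. Under the
#' \eqn{e^{+j\omega t}} convention this is the outgoing cylindrical wave,
#' decaying with distance in a lossy medium.
#'
#' @param point_a,point_b length-2 numeric vectors, cartesian mm.
#' @param k complex background wavenumber, rad/m (see
#'   \code{\link{wavenumber}}).
#' @return complex field factor.
#' @export
greens <- function(point_a, point_b, k) {
  r_mm <- sqrt(sum((point_a - point_b)^2))
  if (r_mm <= 0) stop("greens: coincident points (r = 0 singularity)")
  greens_dist(r_mm, k)
}

# vectorised over distances (mm); kept separate so imaging can batch pixels
greens_dist <- function(r_mm, k) {
  if (any(r_mm <= 0)) stop("greens: non-positive distance")
  (-1i / 4) * hankel02(k * r_mm * 1e-3)
}

# Direct tx->rx coupling for every schedule pair (the instrument baseline)
baseline_channels <- function(geometry, schedule, k) {
  d <- sqrt(rowSums((geometry$tx_pos[schedule$tx, , drop = FALSE] -
                     geometry$rx_pos[schedule$rx, , drop = FALSE])^2))
  greens_dist(d, k)
}

# Scattered field of point scatterers (cross_section rows) on all channels
scattered_channels <- function(geometry, schedule, scatterers, k) {
  out <- complex(nrow(schedule))
  if (nrow(scatterers) == 0) return(out)
  sx <- scatterers$r_mm * cos(scatterers$theta)
  sy <- scatterers$r_mm * sin(scatterers$theta)
  for (s in seq_len(nrow(scatterers))) {
    dt <- sqrt((geometry$tx_pos[schedule$tx, 1] - sx[s])^2 +
               (geometry$tx_pos[schedule$tx, 2] - sy[s])^2)
    dr <- sqrt((geometry$rx_pos[schedule$rx, 1] - sx[s])^2 +
               (geometry$rx_pos[schedule$rx, 2] - sy[s])^2)
    if (any(dt <= 1e-9) || any(dr <= 1e-9)) {
      stop("scatterer coincides with an antenna position")
    }
    out <- out + scatterers$amplitude[s] * scatterers$chi[s] *
      greens_dist(dt, k) * greens_dist(dr, k)
  }
  out
}

#' Simulate the 24-channel measurement of one frame
#'
#' Born-approximation total field: deterministic direct-coupling baseline
#' plus one single-scattering term per scatterer, plus circular complex
#' Gaussian noise. Uses the current RNG state for the noise draw.
#'
#' @param geometry an \code{\link{array_geometry}}.
#' @param schedule the \code{\link{build_schedule}} result.
#' @param scatterers data frame from \code{\link{cross_section}}.
#' @param k complex background wavenumber (rad/m).
#' @param noise_sigma absolute std of the complex noise per quadrature pair
#'   (0 for noise-free).
#' @param frame_idx 0-based frame index recorded on the frame.
#' @return an object of class \code{mw_frame}: fields \code{frame_idx},
#'   \code{data} (complex, one per schedule pair), \code{is_baseline}.
#' @export
simulate_frame <- function(geometry, schedule, scatterers, k,
                           noise_sigma = 0, frame_idx = 0L) {
  base <- baseline_channels(geometry, schedule, k)
  data <- base + scattered_channels(geometry, schedule, scatterers, k)
  if (noise_sigma > 0) {
    n <- nrow(schedule)
    data <- data + complex(
      real = stats::rnorm(n, 0, noise_sigma / sqrt(2)),
      imaginary = stats::rnorm(n, 0, noise_sigma / sqrt(2)))
  }
  structure(list(frame_idx = as.integer(frame_idx), data = data,
                 is_baseline = nrow(scatterers) == 0),
            class = "mw_frame")
}

#' Apply an antenna-mismatch contact event to a frame
#'
#' Affected channels are multiplied by \code{severity} with a random phase
#' drawn uniformly in \code{[-phase_jitter, phase_jitter]} (current RNG
#' state); other channels are untouched.
#'
#' @param frame an \code{mw_frame}.
#' @param event a \code{\link{contact_event}}.
#' @param phase_jitter half-width of the uniform phase perturbation, radians
#'   (default \code{pi}: fully randomised phase).
#' @return the corrupted \code{mw_frame}.
#' @export
apply_contact <- function(frame, event, phase_jitter = pi) {
  stopifnot(inherits(frame, "mw_frame"), inherits(event, "mw_contact"))
  ch <- event$affected_channels
  if (any(ch < 1 | ch > length(frame$data))) {
    stop("affected_channels outside the schedule")
  }
  phi <- stats::runif(length(ch), -phase_jitter, phase_jitter)
  frame$data[ch] <- frame$data[ch] * event$severity * exp(1i * phi)
  frame
}

#' Simulate the full channel stream of a pull-back
#'
#' Runs the forward model over every frame of a timeline: scatterers from
#' \code{\link{cross_section}}, contact corruption applied to the annotated
#' frames, circular complex Gaussian noise with std
#' \code{noise_rel * median(|baseline|)}. Fully reproducible from the seed;
#' the caller's RNG state is left untouched.
#'
#' @param timeline an \code{mw_timeline}.
#' @param geometry an \code{\link{array_geometry}}.
#' @param noise_rel noise std relative to the median baseline channel
#'   magnitude (default 1e-3).
#' @param seed integer seed (defaults to the timeline's seed).
#' @param tissues tissue table used for contrasts and the propagation
#'   background.
#' @return an object of class \code{mw_stream}: \code{channels}
#'   (n_frames x n_pairs complex matrix), \code{baseline} (true direct
#'   coupling, n_pairs), \code{geometry}, \code{schedule}, \code{k_bg},
#'   \code{noise_rel}, \code{noise_sigma}, \code{seed}, \code{truth} (the
#'   \code{\link{ground_truth}} annotation track).
#' @export
simulate_stream <- function(timeline, geometry = array_geometry(),
                            noise_rel = 1e-3, seed = timeline$seed,
                            tissues = default_tissues()) {
  stopifnot(inherits(timeline, "mw_timeline"))
  schedule <- build_schedule(geometry)
  bg <- complex_permittivity(
    resolve_tissue(tissues, timeline$background_tissue), geometry$frequency)
  k <- wavenumber(bg)
  base <- baseline_channels(geometry, schedule, k)
  noise_sigma <- noise_rel * stats::median(Mod(base))
  n <- timeline$n_frames
  npair <- nrow(schedule)
  # contact lookup: which events touch each frame
  contact_at <- vector("list", n)
  for (ct in timeline$contacts) {
    for (f in seq.int(ct$frame_start, ct$frame_start + ct$frame_extent - 1L)) {
      contact_at[[f + 1L]] <- c(contact_at[[f + 1L]], list(ct))
    }
  }
  channels <- matrix(complex(1), n, npair)
  with_seed(seed, {
    for (f in 0:(n - 1L)) {
      sc <- cross_section(timeline, f, tissues, geometry$frequency)
      fr <- simulate_frame(geometry, schedule, sc, k,
                           noise_sigma = noise_sigma, frame_idx = f)
      for (ct in contact_at[[f + 1L]]) fr <- apply_contact(fr, ct)
      channels[f + 1L, ] <- fr$data
    }
  })
  structure(list(
    channels = channels, baseline = base, geometry = geometry,
    schedule = schedule, k_bg = k, noise_rel = noise_rel,
    noise_sigma = noise_sigma, seed = as.integer(seed),
    background_tissue = timeline$background_tissue,
    truth = ground_truth(timeline)
  ), class = "mw_stream")
}

#' @export
print.mw_stream <- function(x, ...) {
  cat(sprintf(
    "<mw_stream> %d frames x %d channels, noise %g (rel %g), seed %d\n",
    nrow(x$channels), ncol(x$channels), x$noise_sigma, x$noise_rel, x$seed))
  invisible(x)
}
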