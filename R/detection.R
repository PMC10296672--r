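# Threshold + run-width detection on the aggregated contrast trace. A
# leading healthy window calibrates the null level; frames whose aggregate
# exceeds mean + k_sigma * sd form candidate runs (short gaps bridged);
# wide runs are called polyps, short ones stool remnants; each run becomes
# one alert event -- the testable form of the acoustic polyp alert.

#' Detector configuration
#'
#' @param k_sigma threshold multiplier over the calibration std (default 5:
#'   near-zero false-alarm rate under Gaussian noise).
#' @param L_min minimum polyp run length in frames (default 10, inclusive;
#'   sits between the default stool extents (<= 6) and polyp extents
#'   (>= 15) with margin on both sides).
#' @param gap_bridge maximum below-threshold or invalid gap bridged inside a
#'   run, frames (default 3).
#' @param calib_frames number of leading valid frames used to calibrate the
#'   detection threshold and the channel baseline (default 50).
#' @return an object of class \code{mw_detector_config}.
#' @export
detector_config <- function(k_sigma = 5, L_min = 10L, gap_bridge = 3L,
                            calib_frames = 50L) {
  stopifnot(k_sigma > 0, L_min >= 1, gap_bridge >= 0, calib_frames >= 2)
  structure(list(k_sigma = k_sigma, L_min = as.integer(L_min),
                 gap_bridge = as.integer(gap_bridge),
                 calib_frames = as.integer(calib_frames)),
            class = "mw_detector_config")
}

#' Calibrate the detection threshold from leading healthy frames
#'
#' \eqn{\theta = \mu + k_\sigma \sigma} of the scalar aggregate over the
#' first \code{calib_frames} valid frames. The leading window is assumed
#' healthy (operator responsibility, as for the channel baseline).
#'
#' @param map an \code{mw_contrast_map}.
#' @param mask an \code{mw_validity} for the same stream.
#' @param config a \code{\link{detector_config}}.
#' @return numeric threshold.
#' @export
calibrate_threshold <- function(map, mask, config = detector_config()) {
  stopifnot(inherits(map, "mw_contrast_map"), inherits(mask, "mw_validity"))
  valid_idx <- which(mask$valid)
  if (length(valid_idx) < config$calib_frames) {
    stop("too few valid frames to calibrate the detection threshold")
  }
  a <- map$aggregate[valid_idx[seq_len(config$calib_frames)]]
  mu <- mean(a)
  s <- stats::sd(a)
  if (length(a) < 2 || is.na(s)) s <- 0
  mu + config$k_sigma * s
}

#' Extract candidate detection runs from a contrast map
#'
#' Candidate frames are valid frames whose aggregate exceeds the threshold.
#' Maximal candidate intervals separated by gaps of at most
#' \code{gap_bridge} frames (below-threshold or invalid) are merged; runs
#' always start and end on candidate (hence valid) frames.
#'
#' @param map an \code{mw_contrast_map}.
#' @param mask an \code{mw_validity}.
#' @param theta_detect detection threshold (>= 0).
#' @param config a \code{\link{detector_config}}.
#' @return data frame with 0-based half-open columns \code{frame_start},
#'   \code{frame_end}, sorted and disjoint.
#' @export
find_runs <- function(map, mask, theta_detect, config = detector_config()) {
  stopifnot(theta_detect >= 0)
  cand <- which(mask$valid & map$aggregate > theta_detect) - 1L # 0-based
  if (length(cand) == 0) {
    return(data.frame(frame_start = integer(), frame_end = integer()))
  }
  new_run <- c(TRUE, diff(cand) > config$gap_bridge + 1L)
  grp <- cumsum(new_run)
  data.frame(
    frame_start = as.integer(tapply(cand, grp, min)),
    frame_end = as.integer(tapply(cand, grp, max)) + 1L,
    row.names = NULL)
}

#' Classify candidate runs into polyp and stool alerts
#'
#' Run width in frames is the discriminant: runs of length at least
#' \code{L_min} (inclusive) are polyps, shorter runs stool remnants. Each
#' run yields one alert event carrying the angular position and magnitude
#' of its contrast peak.
#'
#' @param runs data frame from \code{\link{find_runs}}.
#' @param map the \code{mw_contrast_map} the runs came from.
#' @param config a \code{\link{detector_config}}.
#' @return data frame of class \code{mw_events} with columns
#'   \code{frame_start}, \code{frame_end}, \code{label}, \code{theta_peak},
#'   \code{peak_contrast}.
#' @export
classify_runs <- function(runs, map, config = detector_config()) {
  n <- nrow(runs)
  theta_peak <- numeric(n)
  peak <- numeric(n)
  for (i in seq_len(n)) {
    rows <- (runs$frame_start[i] + 1L):runs$frame_end[i]
    block <- map$profiles[rows, , drop = FALSE]
    j <- which(block == max(block), arr.ind = TRUE)[1, ]
    theta_peak[i] <- map$grid$theta_centers[j[["col"]]]
    peak[i] <- max(block)
  }
  ev <- data.frame(
    frame_start = as.integer(runs$frame_start),
    frame_end = as.integer(runs$frame_end),
    label = ifelse(runs$frame_end - runs$frame_start >= config$L_min,
                   "polyp", "stool"),
    theta_peak = theta_peak, peak_contrast = peak)
  class(ev) <- c("mw_events", "data.frame")
  ev
}

#' End-to-end detection on a channel stream
#'
#' Composes the whole pipeline: channel baseline from the leading window,
#' validity mask, contrast map, threshold calibration, run extraction and
#' run-width classification. Deterministic given the stream.
#'
#' @param stream an \code{mw_stream}.
#' @param grid a \code{\link{polar_grid}}.
#' @param config a \code{\link{detector_config}}.
#' @param tau_chan,m_min validity thresholds (see
#'   \code{\link{classify_validity}}).
#' @return an object of class \code{mw_detection}: \code{events},
#'   \code{map}, \code{mask}, \code{threshold}, \code{baseline},
#'   \code{config}.
#' @export
detect <- function(stream, grid = polar_grid(), config = detector_config(),
                   tau_chan = 0.5, m_min = 2L) {
  stopifnot(inherits(stream, "mw_stream"))
  baseline <- estimate_baseline(stream, config$calib_frames)
  mask <- classify_validity(stream, baseline, tau_chan, m_min)
  map <- build_contrast_map(stream, baseline, grid)
  threshold <- calibrate_threshold(map, mask, config)
  runs <- find_runs(map, mask, threshold, config)
  events <- classify_runs(runs, map, config)
  structure(list(events = events, map = map, mask = mask,
                 threshold = threshold, baseline = baseline,
                 config = config),
            class = "mw_detection")
}

#' @export
print.mw_detection <- function(x, ...) {
  np <- sum(x$events$label == "polyp")
  ns <- sum(x$events$label == "stool")
  cat(sprintf(
    "<mw_detection> %d alert(s): %d polyp, %d stool; threshold %.3g; %d/%d frames valid\n",
    nrow(x$events), np, ns, x$threshold, sum(x$mask$valid),
    length(x$mask$valid)))
  invisible(x)
}

#' @export
summary.mw_detection <- function(object, ...) {
  print(object)
  if (nrow(object$events) > 0) print(as.data.frame(object$events))
  invisible(object)
}

#' Plot the detection result
#'
#' The aggregated contrast trace with the calibrated threshold, invalid
#' frames greyed out, and alert intervals shaded (polyp darker than stool).
#'
#' @param x an \code{mw_detection}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.mw_detection <- function(x, ...) {
  a <- x$map$aggregate
  f <- seq_along(a) - 1L
  graphics::plot(f, a, type = "l", xlab = "frame",
                 ylab = "aggregated contrast (a.u.)", ...)
  if (any(!x$mask$valid)) {
    graphics::points(f[!x$mask$valid], a[!x$mask$valid], col = "grey60",
                     pch = 16, cex = 0.4)
  }
  graphics::abline(h = x$threshold, lty = 2, col = "red")
  for (i in seq_len(nrow(x$events))) {
    col <- if (x$events$label[i] == "polyp") {
      grDevices::adjustcolor("orange", 0.4)
    } else grDevices::adjustcolor("skyblue", 0.4)
    graphics::rect(x$events$frame_start[i], 0, x$events$frame_end[i],
                   max(a), col = col, border = NA)
  }
  invisible(x)
}
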