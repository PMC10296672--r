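# Frame-validity classification: contact with the colon wall or stool
# mismatches specific antennas and corrupts their channels far beyond
# anything a lesion echo produces. The score counts strongly deviating
# channels (a count, not a norm, so one large lesion echo on a single
# channel cannot invalidate a frame).

#' Per-channel mismatch score of a frame
#'
#' Relative deviation \eqn{e_c = |d_c - b_c| / |b_c|} per channel; the score
#' is the number of channels with \eqn{e_c > \tau_{chan}}. Channels whose
#' baseline is exactly zero are excluded (with a warning): their relative
#' deviation is undefined.
#'
#' @param frame an \code{mw_frame} or complex channel vector.
#' @param baseline complex per-channel baseline.
#' @param tau_chan relative-deviation threshold (default 0.5).
#' @return integer score.
#' @export
mismatch_score <- function(frame, baseline, tau_chan = 0.5) {
  data <- if (inherits(frame, "mw_frame")) frame$data else as.complex(frame)
  if (length(data) != length(baseline)) {
    stop("frame and baseline lengths differ")
  }
  ok <- Mod(baseline) > 0
  if (!all(ok)) warning("zero-baseline channel(s) excluded from the score")
  sum(Mod(data[ok] - baseline[ok]) / Mod(baseline[ok]) > tau_chan)
}

#' Classify the validity of every frame in a stream
#'
#' A frame is invalid (contact-corrupted) iff its mismatch score reaches
#' \code{m_min} channels. The defaults (\code{tau_chan = 0.5},
#' \code{m_min = 2}) sit far above lesion-induced deviations and far below
#' contact severities, so simulated polyps never trip validity.
#'
#' @param stream an \code{mw_stream}.
#' @param baseline complex per-channel baseline.
#' @param tau_chan per-channel relative-deviation threshold.
#' @param m_min minimum number of deviating channels (>= 1).
#' @return an object of class \code{mw_validity}: \code{valid} (logical
#'   per frame), \code{score} (integer per frame), thresholds.
#' @export
classify_validity <- function(stream, baseline, tau_chan = 0.5, m_min = 2L) {
  stopifnot(inherits(stream, "mw_stream"), m_min >= 1)
  ok <- Mod(baseline) > 0
  if (!all(ok)) warning("zero-baseline channel(s) excluded from the score")
  dev <- sweep(Mod(sweep(stream$channels[, ok, drop = FALSE], 2,
                         baseline[ok], "-")), 2, Mod(baseline[ok]), "/")
  score <- as.integer(rowSums(dev > tau_chan))
  structure(list(valid = score < m_min, score = score,
                 tau_chan = tau_chan, m_min = as.integer(m_min)),
            class = "mw_validity")
}

#' @export
print.mw_validity <- function(x, ...) {
  s <- validity_summary(x)
  cat(sprintf("<mw_validity> %d frames, %d invalid (%.1f%%)\n",
              s$n_frames, s$n_invalid, 100 * s$invalid_fraction))
  invisible(x)
}

#' Summary counts of a validity mask
#'
#' @param mask an \code{mw_validity}.
#' @return list with \code{n_frames}, \code{n_invalid},
#'   \code{invalid_fraction}.
#' @export
validity_summary <- function(mask) {
  stopifnot(inherits(mask, "mw_validity"))
  n <- length(mask$valid)
  if (n == 0) stop("empty validity mask")
  list(n_frames = n, n_invalid = sum(!mask$valid),
       invalid_fraction = sum(!mask$valid) / n)
}

# validity mask as a 0-based half-open interval track (for TSV export)
validity_intervals <- function(mask) {
  lab <- ifelse(mask$valid, "valid", "invalid_contact")
  labels_to_intervals(lab)
}
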