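# Segment-level scoring against ground truth, and the two replica
# experiments: the valid 600-frame sequence (3 isolated polyps, 4 healthy
# stretches) and the recovery of the second trial's contact-discard rate on
# a long corrupted stream.

#' Score alert events against a ground-truth annotation track
#'
#' Segments are the contiguous same-label intervals of the truth track. A
#' polyp segment counts as detected iff at least one polyp-labelled event
#' overlaps it by one frame or more; a healthy segment overlapped by any
#' polyp event is a false-positive segment; a stool segment overlapped by a
#' polyp event is misclassified. Cluster- and contact-labelled segments are
#' excluded from every count (those frames are not scoreable).
#'
#' @param events an \code{mw_events} data frame (may have zero rows).
#' @param truth an \code{mw_annotation} track on the same frame axis.
#' @return an object of class \code{mw_segment_score}: per-segment table
#'   plus totals \code{polyp_segments}, \code{polyp_detected},
#'   \code{healthy_segments}, \code{healthy_with_false_polyp},
#'   \code{stool_misclassified_as_polyp}.
#' @export
score_segments <- function(events, truth) {
  stopifnot(inherits(truth, "mw_annotation"))
  n_frames <- if (nrow(truth)) max(truth$frame_end) else 0L
  if (nrow(events) > 0 &&
      (min(events$frame_start) < min(truth$frame_start) ||
       max(events$frame_end) > n_frames)) {
    stop("events extend outside the annotated frame range")
  }
  pol <- events[events$label == "polyp", , drop = FALSE]
  overlaps_polyp <- function(s, e) {
    nrow(pol) > 0 && any(pol$frame_start < e & pol$frame_end > s)
  }
  seg <- truth
  seg$scored <- !(seg$label %in% c("cluster", "contact"))
  seg$detected <- vapply(seq_len(nrow(seg)), function(i) {
    seg$scored[i] && overlaps_polyp(seg$frame_start[i], seg$frame_end[i])
  }, logical(1))
  totals <- list(
    polyp_segments = sum(seg$scored & seg$label == "polyp"),
    polyp_detected = sum(seg$scored & seg$label == "polyp" & seg$detected),
    healthy_segments = sum(seg$scored & seg$label == "healthy"),
    healthy_with_false_polyp =
      sum(seg$scored & seg$label == "healthy" & seg$detected),
    stool_misclassified_as_polyp =
      sum(seg$scored & seg$label == "stool" & seg$detected))
  structure(c(list(segments = seg), totals), class = "mw_segment_score")
}

#' @export
print.mw_segment_score <- function(x, ...) {
  cat(sprintf(
    "<mw_segment_score> polyp %d/%d detected; healthy false-positive %d/%d; stool-as-polyp %d\n",
    x$polyp_detected, x$polyp_segments, x$healthy_with_false_polyp,
    x$healthy_segments, x$stool_misclassified_as_polyp))
  invisible(x)
}

#' Run the 600-frame replica experiment
#'
#' Generates the replica timeline (3 isolated polyps, 4 healthy stretches,
#' no contacts), simulates the channel stream, runs the full detection
#' pipeline with the given configuration, and scores the alerts against
#' ground truth segment by segment.
#'
#' @param seed integer seed driving scene and noise.
#' @param config a pipeline configuration (see \code{\link{default_config}}).
#' @return list with \code{polyp_segments}, \code{polyp_detected},
#'   \code{healthy_segments}, \code{healthy_with_false_polyp},
#'   \code{stool_misclassified_as_polyp}, \code{events}, \code{map},
#'   \code{truth}, \code{detection}, \code{seed}.
#' @export
run_replica_sequence <- function(seed = 0L, config = default_config()) {
  timeline <- replica_sequence_timeline(
    seed, amplitude = config$scene$polyp_amplitude)
  stream <- simulate_stream(
    timeline, geometry = config_geometry(config),
    noise_rel = config$noise$rel_sigma, seed = seed,
    tissues = config_tissues(config))
  det <- detect(stream, grid = config_grid(config),
                config = config_detector(config),
                tau_chan = config$quality$tau_chan,
                m_min = config$quality$m_min)
  sc <- score_segments(det$events, stream$truth)
  list(polyp_segments = sc$polyp_segments,
       polyp_detected = sc$polyp_detected,
       healthy_segments = sc$healthy_segments,
       healthy_with_false_polyp = sc$healthy_with_false_polyp,
       stool_misclassified_as_polyp = sc$stool_misclassified_as_polyp,
       events = det$events, map = det$map, truth = stream$truth,
       detection = det, seed = as.integer(seed))
}

#' Recover the contact-discard rate on a long corrupted stream
#'
#' Generates a random pull-back whose per-frame contact probability is
#' \code{contact_fraction}, simulates it, classifies frame validity against
#' the estimated baseline, and reports the recovered invalid fraction next
#' to the generator truth.
#'
#' @param n_frames stream length (the study's second trial recorded 7087).
#' @param seed integer seed.
#' @param config pipeline configuration.
#' @param contact_fraction generator per-frame contact probability
#'   (default 0.14).
#' @return list with \code{n_frames}, \code{true_contact_fraction} (realised
#'   fraction of contact-labelled frames), \code{estimated_invalid_fraction},
#'   \code{estimated_invalid_percent}, \code{seed}.
#' @export
run_trial2_recovery <- function(n_frames = 7087L, seed = 0L,
                                config = default_config(),
                                contact_fraction = 0.14) {
  stopifnot(n_frames >= 1)
  timeline <- random_timeline(
    n_frames, contact_fraction = contact_fraction, seed = seed,
    amplitude = config$scene$polyp_amplitude,
    severity = config$scene$contact_severity)
  stream <- simulate_stream(
    timeline, geometry = config_geometry(config),
    noise_rel = config$noise$rel_sigma, seed = seed,
    tissues = config_tissues(config))
  baseline <- estimate_baseline(stream,
                                window = config$detector$calib_frames)
  mask <- classify_validity(stream, baseline,
                            tau_chan = config$quality$tau_chan,
                            m_min = config$quality$m_min)
  s <- validity_summary(mask)
  truth_contact <- sum(with(stream$truth,
                            (frame_end - frame_start)[label == "contact"]))
  list(n_frames = as.integer(n_frames),
       true_contact_fraction = truth_contact / n_frames,
       estimated_invalid_fraction = s$invalid_fraction,
       estimated_invalid_percent = 100 * s$invalid_fraction,
       seed = as.integer(seed))
}
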