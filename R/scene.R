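# Synthetic colon scenes: pull-back timelines carrying polyp and stool
# inclusions, wall-contact events, and the ground-truth annotation track
# derived from them. Frames are the longitudinal unit (no pull-back speed is
# modelled); all frame intervals are 0-based and half-open [start, end).

# Run code with a private RNG stream, restoring the caller's state after.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' A single scene inclusion (polyp or stool remnant)
#'
#' An inclusion is a point scatterer persisting over a run of frames. Polyps
#' default to long runs and stool remnants to short ones: run width along the
#' pull-back is the discriminant the detector ultimately uses.
#'
#' @param kind \code{"polyp"} or \code{"stool"}.
#' @param theta_center angular position, radians in [0, 2*pi).
#' @param frame_start first frame (0-based integer).
#' @param frame_extent number of frames the inclusion spans (>= 1).
#' @param theta_width angular width in radians (> 0; descriptive, the forward
#'   model treats the inclusion as a point).
#' @param radial_offset distance from the lumen wall inward, mm.
#' @param tissue_class tissue name resolved against the tissue table.
#' @param amplitude dimensionless scattering strength scale (> 0).
#' @return an object of class \code{mw_inclusion}.
#' @export
inclusion <- function(kind = c("polyp", "stool"), theta_center, frame_start,
                      frame_extent, theta_width = 0.3, radial_offset = 2,
                      tissue_class = if (kind == "polyp") "adenoma" else "stool",
                      amplitude = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(theta_center), length(theta_center) == 1L)
  if (theta_width <= 0) stop("theta_width must be > 0")
  if (frame_extent < 1) stop("frame_extent must be >= 1")
  if (frame_start < 0) stop("frame_start must be >= 0")
  if (amplitude <= 0) stop("amplitude must be > 0")
  structure(list(
    kind = kind, theta_center = theta_center %% (2 * pi),
    theta_width = theta_width, frame_start = as.integer(frame_start),
    frame_extent = as.integer(frame_extent), radial_offset = radial_offset,
    tissue_class = tissue_class, amplitude = amplitude
  ), class = "mw_inclusion")
}

#' A wall/stool contact event corrupting antenna channels
#'
#' While the accessory touches the mucosa or stool, the affected antennas are
#' mismatched: their channels are multiplied by a severity factor with a
#' random phase, destroying the calibration those frames rely on.
#'
#' @param frame_start first affected frame (0-based).
#' @param frame_extent number of affected frames (>= 1).
#' @param affected_channels schedule row indices (1-based, non-empty).
#' @param severity multiplicative mismatch factor (> 1 for a real contact).
#' @return an object of class \code{mw_contact}.
#' @export
contact_event <- function(frame_start, frame_extent, affected_channels,
                          severity = 10) {
  if (length(affected_channels) == 0) {
    stop("affected_channels must be non-empty")
  }
  if (frame_extent < 1) stop("frame_extent must be >= 1")
  structure(list(
    frame_start = as.integer(frame_start),
    frame_extent = as.integer(frame_extent),
    affected_channels = as.integer(sort(unique(affected_channels))),
    severity = severity
  ), class = "mw_contact")
}

#' Longitudinal scene timeline for a simulated pull-back
#'
#' @param n_frames number of frames in the pull-back.
#' @param lumen_radius lumen wall radius in mm (default 15).
#' @param background_tissue background tissue class name (default
#'   \code{"mucosa"}).
#' @param inclusions list of \code{\link{inclusion}} objects.
#' @param contacts list of \code{\link{contact_event}} objects.
#' @param seed integer seed recorded with the timeline.
#' @return an object of class \code{mw_timeline}.
#' @export
scene_timeline <- function(n_frames, lumen_radius = 15,
                           background_tissue = "mucosa",
                           inclusions = list(), contacts = list(),
                           seed = 0L) {
  stopifnot(n_frames >= 1)
  for (inc in inclusions) {
    stopifnot(inherits(inc, "mw_inclusion"))
    if (inc$frame_start + inc$frame_extent > n_frames) {
      stop("inclusion interval extends past the end of the timeline")
    }
  }
  for (ct in contacts) {
    stopifnot(inherits(ct, "mw_contact"))
    if (ct$frame_start + ct$frame_extent > n_frames) {
      stop("contact interval extends past the end of the timeline")
    }
  }
  structure(list(
    n_frames = as.integer(n_frames), lumen_radius = lumen_radius,
    background_tissue = background_tissue, inclusions = inclusions,
    contacts = contacts, seed = as.integer(seed)
  ), class = "mw_timeline")
}

#' @export
print.mw_timeline <- function(x, ...) {
  kinds <- vapply(x$inclusions, `[[`, "", "kind")
  cat(sprintf(
    "<mw_timeline> %d frames, %d polyp(s), %d stool, %d contact event(s), seed %d\n",
    x$n_frames, sum(kinds == "polyp"), sum(kinds == "stool"),
    length(x$contacts), x$seed))
  invisible(x)
}

#' Point scatterers active in one cross-sectional frame
#'
#' Each inclusion active at \code{frame_idx} contributes one point scatterer
#' at radius \code{lumen_radius - radial_offset} and angle
#' \code{theta_center}, with the dielectric contrast of its tissue class
#' against the timeline background.
#'
#' @param timeline an \code{mw_timeline}.
#' @param frame_idx 0-based frame index.
#' @param tissues tissue table (named list of \code{\link{dielectric_props}}).
#' @param frequency working frequency, Hz.
#' @return data frame with one row per active inclusion: \code{kind},
#'   \code{r_mm}, \code{theta}, \code{chi} (complex), \code{amplitude}; rows
#'   in inclusion-list order. Zero rows when no inclusion is active.
#' @export
cross_section <- function(timeline, frame_idx, tissues = default_tissues(),
                          frequency = 7.5e9) {
  stopifnot(inherits(timeline, "mw_timeline"))
  if (frame_idx < 0 || frame_idx >= timeline$n_frames) {
    stop(sprintf("frame_idx %d out of range [0, %d)", frame_idx,
                 timeline$n_frames))
  }
  bg <- complex_permittivity(
    resolve_tissue(tissues, timeline$background_tissue), frequency)
  active <- Filter(function(inc) {
    frame_idx >= inc$frame_start &&
      frame_idx < inc$frame_start + inc$frame_extent
  }, timeline$inclusions)
  if (length(active) == 0) {
    return(data.frame(kind = character(), r_mm = numeric(),
                      theta = numeric(), chi = complex(),
                      amplitude = numeric()))
  }
  chi <- vapply(active, function(inc) {
    dielectric_contrast(
      complex_permittivity(resolve_tissue(tissues, inc$tissue_class),
                           frequency), bg)
  }, complex(1))
  data.frame(
    kind = vapply(active, `[[`, "", "kind"),
    r_mm = timeline$lumen_radius -
      vapply(active, `[[`, 0, "radial_offset"),
    theta = vapply(active, `[[`, 0, "theta_center"),
    chi = chi,
    amplitude = vapply(active, `[[`, 0, "amplitude")
  )
}

# Per-frame label vector with priority contact > cluster > polyp > stool >
# healthy; frames covered by two or more polyp inclusions are `cluster`.
frame_labels <- function(timeline) {
  n <- timeline$n_frames
  polyp_cov <- integer(n)
  stool_cov <- integer(n)
  for (inc in timeline$inclusions) {
    idx <- seq.int(inc$frame_start + 1L, inc$frame_start + inc$frame_extent)
    if (inc$kind == "polyp") polyp_cov[idx] <- polyp_cov[idx] + 1L
    else stool_cov[idx] <- stool_cov[idx] + 1L
  }
  lab <- rep("healthy", n)
  lab[stool_cov > 0] <- "stool"
  lab[polyp_cov == 1] <- "polyp"
  lab[polyp_cov >= 2] <- "cluster"
  for (ct in timeline$contacts) {
    idx <- seq.int(ct$frame_start + 1L, ct$frame_start + ct$frame_extent)
    lab[idx] <- "contact"
  }
  lab
}

# Collapse a per-frame label vector to 0-based half-open intervals
labels_to_intervals <- function(lab) {
  r <- rle(lab)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  annotation_track(data.frame(frame_start = start, frame_end = end,
                              label = r$values))
}

#' Annotation track constructor/validator
#'
#' An annotation track is an ordered set of 0-based, half-open frame
#' intervals, each carrying a label; consecutive intervals tile the frame
#' axis without gaps or overlap.
#'
#' @param df data frame with columns \code{frame_start}, \code{frame_end},
#'   \code{label}.
#' @return the data frame with class \code{mw_annotation}.
#' @export
annotation_track <- function(df) {
  stopifnot(all(c("frame_start", "frame_end", "label") %in% names(df)))
  if (nrow(df) > 0) {
    if (any(df$frame_end <= df$frame_start)) {
      stop("annotation intervals must satisfy frame_end > frame_start")
    }
    if (nrow(df) > 1 &&
        any(df$frame_start[-1] != df$frame_end[-nrow(df)])) {
      stop("annotation intervals must tile the frame axis contiguously")
    }
  }
  df$frame_start <- as.integer(df$frame_start)
  df$frame_end <- as.integer(df$frame_end)
  df$label <- as.character(df$label)
  rownames(df) <- NULL
  class(df) <- c("mw_annotation", "data.frame")
  df
}

#' Ground-truth annotation track of a timeline
#'
#' Labels every frame, with priority \code{contact > cluster > polyp > stool
#' > healthy}: contact frames are unusable whatever they contain, and frames
#' covered by overlapping polyps are marked \code{cluster} (excluded from
#' scoring, mirroring how densely polyp-covered stretches cannot be annotated
#' as isolated lesions).
#'
#' @param timeline an \code{mw_timeline}.
#' @return an \code{mw_annotation} data frame tiling \code{[0, n_frames)}.
#' @export
ground_truth <- function(timeline) {
  stopifnot(inherits(timeline, "mw_timeline"))
  labels_to_intervals(frame_labels(timeline))
}

# Schedule rows touching a given antenna under the default co-indexed layout
antenna_channels <- function(antenna, n_antennas = 8L) {
  sched <- schedule_pairs(n_antennas)
  which(sched$tx == antenna | sched$rx == antenna)
}

#' Random pull-back timeline
#'
#' Draws a reproducible timeline with Poisson-placed inclusions and
#' Bernoulli-per-frame contact corruption. Contact frames are marked
#' independently with probability \code{contact_fraction}, then merged into
#' contact events each tied to one or two touched antennas (all schedule
#' channels involving those antennas are corrupted), so the realised
#' contact-frame fraction fluctuates binomially around the request.
#'
#' @param n_frames timeline length.
#' @param polyp_rate expected polyps per frame (default 1/200).
#' @param stool_rate expected stool remnants per frame (default 1/150).
#' @param contact_fraction per-frame contact probability in [0, 1).
#' @param cluster if \code{TRUE}, each polyp placement becomes an overlapping
#'   group of 2--3 polyps whose overlap is annotated \code{cluster}.
#' @param seed integer seed; identical seeds give identical timelines.
#' @param polyp_extent,stool_extent inclusive integer ranges of run lengths
#'   in frames; polyp runs are wide, stool runs short.
#' @param lumen_radius,radial_offset scene geometry, mm.
#' @param amplitude scattering strength for every inclusion.
#' @param severity contact mismatch factor.
#' @return an \code{mw_timeline}.
#' @export
random_timeline <- function(n_frames, polyp_rate = 1 / 200,
                            stool_rate = 1 / 150, contact_fraction = 0,
                            cluster = FALSE, seed = 0L,
                            polyp_extent = c(15L, 40L),
                            stool_extent = c(2L, 6L),
                            lumen_radius = 15, radial_offset = 2,
                            amplitude = 1, severity = 10) {
  stopifnot(polyp_rate >= 0, stool_rate >= 0,
            contact_fraction >= 0, contact_fraction < 1)
  expected_cov <- polyp_rate * mean(polyp_extent) * (if (cluster) 2.5 else 1) +
    stool_rate * mean(stool_extent)
  if (expected_cov > 0.8) {
    stop("infeasible packing: inclusion rates too high for the timeline")
  }
  with_seed(seed, {
    incs <- list()
    n_polyp <- stats::rpois(1, polyp_rate * n_frames)
    n_stool <- stats::rpois(1, stool_rate * n_frames)
    add_inc <- function(kind, extent_range) {
      ext <- sample(seq.int(extent_range[1], extent_range[2]), 1)
      ext <- min(ext, n_frames)
      start <- sample.int(n_frames - ext + 1L, 1) - 1L
      inclusion(kind, theta_center = stats::runif(1, 0, 2 * pi),
                frame_start = start, frame_extent = ext,
                radial_offset = radial_offset, amplitude = amplitude)
    }
    for (i in seq_len(n_polyp)) {
      base <- add_inc("polyp", polyp_extent)
      incs <- c(incs, list(base))
      if (cluster) {
        for (j in seq_len(sample(1:2, 1))) { # overlapping companions
          shift <- sample.int(max(1L, base$frame_extent %/% 2L), 1)
          start <- min(max(0L, base$frame_start + shift),
                       n_frames - base$frame_extent)
          incs <- c(incs, list(inclusion(
            "polyp", theta_center = stats::runif(1, 0, 2 * pi),
            frame_start = start, frame_extent = base$frame_extent,
            radial_offset = radial_offset, amplitude = amplitude)))
        }
      }
    }
    for (i in seq_len(n_stool)) {
      incs <- c(incs, list(add_inc("stool", stool_extent)))
    }
    contacts <- list()
    if (contact_fraction > 0) {
      hit <- stats::runif(n_frames) < contact_fraction
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      for (i in which(r$values)) {
        ants <- sample.int(8L, sample(1:2, 1))
        contacts <- c(contacts, list(contact_event(
          frame_start = starts[i], frame_extent = r$lengths[i],
          affected_channels = unique(unlist(lapply(ants, antenna_channels))),
          severity = severity)))
      }
    }
    scene_timeline(n_frames, lumen_radius = lumen_radius,
                   inclusions = incs, contacts = contacts, seed = seed)
  })
}

#' Replica of the valid 600-frame study sequence
#'
#' A 600-frame contact-free pull-back with exactly three isolated polyps
#' separated by healthy stretches, yielding four healthy segments (healthy /
#' polyp / healthy / polyp / healthy / polyp / healthy). Polyp positions and
#' extents vary with the seed; the segment composition never does. The
#' leading healthy stretch always covers the calibration window.
#'
#' @param seed integer seed.
#' @param n_stool number of short stool remnants to drop into healthy
#'   stretches (default 0, giving the clean 3-polyp/4-healthy composition).
#' @param amplitude scattering strength of every inclusion.
#' @return an \code{mw_timeline} with 600 frames.
#' @export
replica_sequence_timeline <- function(seed = 0L, n_stool = 0L, amplitude = 1) {
  n_frames <- 600L
  n_polyp <- 3L
  min_healthy <- 60L # every healthy stretch at least this long (calibration)
  with_seed(seed, {
    extents <- sample(15:40, n_polyp, replace = TRUE)
    slack <- n_frames - sum(extents) - (n_polyp + 1L) * min_healthy
    # split the slack over the 4 healthy stretches
    cuts <- sort(sample.int(slack + 1L, n_polyp, replace = TRUE) - 1L)
    gaps <- min_healthy + diff(c(0L, cuts, slack))
    incs <- list()
    pos <- 0L
    for (i in seq_len(n_polyp)) {
      pos <- pos + gaps[i]
      incs <- c(incs, list(inclusion(
        "polyp", theta_center = stats::runif(1, 0, 2 * pi),
        frame_start = pos, frame_extent = extents[i],
        amplitude = amplitude)))
      pos <- pos + extents[i]
    }
    if (n_stool > 0) {
      # short remnants inside later healthy stretches, keeping the leading
      # calibration window clean
      for (i in seq_len(n_stool)) {
        gap_i <- sample(2:(n_polyp + 1L), 1)
        gstart <- if (gap_i == 1L) 0L else {
          incs[[gap_i - 1L]]$frame_start + incs[[gap_i - 1L]]$frame_extent
        }
        ext <- sample(2:6, 1)
        start <- gstart + sample.int(min_healthy - ext, 1)
        incs <- c(incs, list(inclusion(
          "stool", theta_center = stats::runif(1, 0, 2 * pi),
          frame_start = start, frame_extent = ext, amplitude = amplitude)))
      }
    }
    scene_timeline(n_frames, inclusions = incs, seed = seed)
  })
}
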