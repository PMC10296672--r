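# Configuration and on-disk formats. Everything is plain text and
# self-describing: YAML for the pipeline configuration, a TSV with a JSON
# metadata header for channel-stream archives, BED-like TSV for interval
# tracks (0-based, half-open), JSON for reports.

MW_STREAM_SCHEMA <- 1L

#' Default pipeline configuration
#'
#' One validated document holding every tunable of the pipeline: tissue
#' dielectric table, array geometry, reconstruction grid, scene defaults,
#' noise level, validity thresholds and detector settings.
#'
#' @return a named list of class \code{mw_config}.
#' @export
default_config <- function() {
  cfg <- list(
    tissues = list(
      mucosa = list(eps_r = 50, sigma = 6),
      adenoma = list(eps_r = 60, sigma = 8),
      stool = list(eps_r = 40, sigma = 4)),
    geometry = list(n_antennas = 8L, ring_radius_mm = 10,
                    frequency_hz = 7.5e9, rx_offset_deg = 22.5),
    grid = list(n_r = 20L, r_min_mm = 10.5, r_max_mm = 25, n_theta = 64L,
                antenna_clearance_mm = 0.5),
    scene = list(background_tissue = "mucosa", polyp_tissue = "adenoma",
                 stool_tissue = "stool", lumen_radius_mm = 15,
                 radial_offset_mm = 2, polyp_amplitude = 1,
                 stool_amplitude = 1, contact_severity = 10),
    noise = list(rel_sigma = 1e-3),
    quality = list(tau_chan = 0.5, m_min = 2L),
    detector = list(k_sigma = 5, L_min = 10L, gap_bridge = 3L,
                    calib_frames = 50L))
  class(cfg) <- c("mw_config", "list")
  validate_config(cfg)
}

# flatten nested names as a.b.c for key comparison
flat_keys <- function(x, prefix = NULL) {
  out <- character()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]]))) {
      out <- c(out, flat_keys(x[[nm]], key))
    } else {
      out <- c(out, key)
    }
  }
  out
}

#' Validate a pipeline configuration
#'
#' Checks the document against the default schema: unknown keys are an
#' error (listed by name), as are missing keys, tissue classes referenced
#' but not defined, and an angular bin count not divisible by the antenna
#' count.
#'
#' @param config a configuration list.
#' @return the validated config, classed \code{mw_config}, invisibly usable.
#' @export
validate_config <- function(config) {
  template <- list(
    tissues = NULL, geometry = default_config_section("geometry"),
    grid = default_config_section("grid"),
    scene = default_config_section("scene"),
    noise = default_config_section("noise"),
    quality = default_config_section("quality"),
    detector = default_config_section("detector"))
  # key check: tissues section has free-form names, fixed leaf keys
  known <- unlist(lapply(names(template)[-1], function(s) {
    paste(s, names(template[[s]]), sep = ".")
  }))
  got <- flat_keys(config)
  got_tissue <- grep("^tissues\\.", got, value = TRUE)
  bad_tissue <- got_tissue[!grepl("^tissues\\.[^.]+\\.(eps_r|sigma)$",
                                  got_tissue)]
  other <- setdiff(got, got_tissue)
  unknown <- c(setdiff(other, known), bad_tissue)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(known, other)
  if (length(missing)) {
    stop("missing configuration key(s): ", paste(missing, collapse = ", "))
  }
  if (length(config$tissues) == 0) stop("no tissue classes defined")
  for (ref in c("background_tissue", "polyp_tissue", "stool_tissue")) {
    nm <- config$scene[[ref]]
    if (!nm %in% names(config$tissues)) {
      stop(sprintf("scene.%s references undefined tissue class '%s'",
                   ref, nm))
    }
  }
  if (config$grid$n_theta %% config$geometry$n_antennas != 0) {
    stop("grid.n_theta must be divisible by geometry.n_antennas")
  }
  class(config) <- c("mw_config", "list")
  config
}

# leaf template of one config section (keys only matter for validation)
default_config_section <- function(section) {
  switch(section,
    geometry = list(n_antennas = NA, ring_radius_mm = NA, frequency_hz = NA,
                    rx_offset_deg = NA),
    grid = list(n_r = NA, r_min_mm = NA, r_max_mm = NA, n_theta = NA,
                antenna_clearance_mm = NA),
    scene = list(background_tissue = NA, polyp_tissue = NA,
                 stool_tissue = NA, lumen_radius_mm = NA,
                 radial_offset_mm = NA, polyp_amplitude = NA,
                 stool_amplitude = NA, contact_severity = NA),
    noise = list(rel_sigma = NA),
    quality = list(tau_chan = NA, m_min = NA),
    detector = list(k_sigma = NA, L_min = NA, gap_bridge = NA,
                    calib_frames = NA))
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path file path.
#' @return \code{read_config} returns a validated \code{mw_config};
#'   \code{write_config} returns the path invisibly. The pair round-trips:
#'   \code{read_config(write_config(cfg, p))} equals \code{cfg}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  # yaml drops integer-ness; restore it on known integer keys
  for (k in c("n_antennas")) cfg$geometry[[k]] <- as.integer(cfg$geometry[[k]])
  for (k in c("n_r", "n_theta")) cfg$grid[[k]] <- as.integer(cfg$grid[[k]])
  cfg$quality$m_min <- as.integer(cfg$quality$m_min)
  for (k in c("L_min", "gap_bridge", "calib_frames")) {
    cfg$detector[[k]] <- as.integer(cfg$detector[[k]])
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param config an \code{mw_config}.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# materialise runtime objects from a config document
config_geometry <- function(config) {
  array_geometry(n_antennas = config$geometry$n_antennas,
                 ring_radius = config$geometry$ring_radius_mm,
                 frequency = config$geometry$frequency_hz,
                 rx_offset = config$geometry$rx_offset_deg * pi / 180)
}
config_grid <- function(config) {
  polar_grid(n_r = config$grid$n_r, r_min = config$grid$r_min_mm,
             r_max = config$grid$r_max_mm, n_theta = config$grid$n_theta,
             antenna_clearance = config$grid$antenna_clearance_mm)
}
config_tissues <- function(config) {
  lapply(config$tissues, function(t) dielectric_props(t$eps_r, t$sigma))
}
config_detector <- function(config) {
  detector_config(k_sigma = config$detector$k_sigma,
                  L_min = config$detector$L_min,
                  gap_bridge = config$detector$gap_bridge,
                  calib_frames = config$detector$calib_frames)
}

#' Write / read a channel-stream archive
#'
#' A single TSV file: a \code{#mwstream} header line with the schema
#' version, a \code{#meta} line holding geometry, schedule, true baseline,
#' noise parameters, seed and ground-truth annotation as JSON, then one row
#' per frame with real/imaginary channel columns at full double precision.
#' The round-trip is lossless.
#'
#' @param stream an \code{mw_stream}.
#' @param path file path (conventionally \code{*.mwstream.tsv}).
#' @return \code{write_stream} returns the path invisibly;
#'   \code{read_stream} the reconstructed \code{mw_stream}.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "mw_stream"))
  g <- stream$geometry
  meta <- list(
    schema = MW_STREAM_SCHEMA, n_frames = nrow(stream$channels),
    n_pairs = ncol(stream$channels),
    geometry = list(n_antennas = g$n_tx, ring_radius_mm = g$ring_radius,
                    frequency_hz = g$frequency,
                    rx_offset_rad = (g$rx_angles[1] - g$tx_angles[1])),
    schedule = list(tx = stream$schedule$tx - 1L,
                    rx = stream$schedule$rx - 1L), # 0-based on disk
    # floats as %.17g strings: JSON number emission rounds the last bits
    baseline_re = sprintf("%.17g", Re(stream$baseline)),
    baseline_im = sprintf("%.17g", Im(stream$baseline)),
    k_bg_re = sprintf("%.17g", Re(stream$k_bg)),
    k_bg_im = sprintf("%.17g", Im(stream$k_bg)),
    noise_rel = sprintf("%.17g", stream$noise_rel),
    noise_sigma = sprintf("%.17g", stream$noise_sigma),
    seed = stream$seed, background_tissue = stream$background_tissue,
    truth = list(frame_start = stream$truth$frame_start,
                 frame_end = stream$truth$frame_end,
                 label = stream$truth$label))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#mwstream\t%d", MW_STREAM_SCHEMA), con)
  writeLines(paste0("#meta\t", jsonlite::toJSON(meta, digits = NA,
                                                auto_unbox = TRUE)), con)
  npair <- ncol(stream$channels)
  writeLines(paste(c("frame_idx", paste0(
    rep(sprintf("ch%02d", seq_len(npair)), each = 2),
    c("_re", "_im"))), collapse = "\t"), con)
  reim <- matrix(0, nrow(stream$channels), 2 * npair)
  reim[, 2 * seq_len(npair) - 1] <- Re(stream$channels)
  reim[, 2 * seq_len(npair)] <- Im(stream$channels)
  body <- cbind(seq_len(nrow(stream$channels)) - 1L, reim)
  writeLines(apply(body, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  }), con)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("stream archive not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#mwstream\t")) {
    stop("not a channel-stream archive (missing #mwstream header)")
  }
  ver <- as.integer(sub("#mwstream\t", "", lines[1]))
  if (is.na(ver) || ver != MW_STREAM_SCHEMA) {
    stop(sprintf("stream archive schema version %s does not match %d",
                 lines[1], MW_STREAM_SCHEMA))
  }
  if (!startsWith(lines[2], "#meta\t")) {
    stop("malformed stream archive: missing #meta line")
  }
  meta <- jsonlite::fromJSON(sub("^#meta\t", "", lines[2]))
  body <- lines[-(1:3)]
  if (length(body) != meta$n_frames) {
    stop(sprintf("truncated or padded archive: %d data rows, expected %d",
                 length(body), meta$n_frames))
  }
  vals <- matrix(NA_real_, meta$n_frames, 1 + 2 * meta$n_pairs)
  for (i in seq_along(body)) {
    vals[i, ] <- as.numeric(strsplit(body[i], "\t", fixed = TRUE)[[1]])
  }
  re <- vals[, 1 + 2 * seq_len(meta$n_pairs) - 1, drop = FALSE]
  im <- vals[, 1 + 2 * seq_len(meta$n_pairs), drop = FALSE]
  geometry <- array_geometry(
    n_antennas = meta$geometry$n_antennas,
    ring_radius = meta$geometry$ring_radius_mm,
    frequency = meta$geometry$frequency_hz,
    rx_offset = meta$geometry$rx_offset_rad)
  schedule <- data.frame(tx = meta$schedule$tx + 1L,
                         rx = meta$schedule$rx + 1L)
  class(schedule) <- c("mw_schedule", "data.frame")
  structure(list(
    channels = matrix(complex(real = re, imaginary = im),
                      meta$n_frames, meta$n_pairs),
    baseline = complex(real = as.numeric(meta$baseline_re),
                       imaginary = as.numeric(meta$baseline_im)),
    geometry = geometry, schedule = schedule,
    k_bg = complex(real = as.numeric(meta$k_bg_re),
                   imaginary = as.numeric(meta$k_bg_im)),
    noise_rel = as.numeric(meta$noise_rel),
    noise_sigma = as.numeric(meta$noise_sigma),
    seed = as.integer(meta$seed),
    background_tissue = meta$background_tissue,
    truth = annotation_track(data.frame(
      frame_start = meta$truth$frame_start,
      frame_end = meta$truth$frame_end, label = meta$truth$label))
  ), class = "mw_stream")
}

#' Write / read an interval track (BED-like TSV)
#'
#' Columns \code{frame_start}, \code{frame_end}, \code{label} plus any extra
#' event columns; 0-based, half-open, stated in the file header. Reading
#' validates each interval (\code{frame_end > frame_start}) and rejects
#' overlapping intervals sharing a label lane. An empty file yields an
#' empty track.
#'
#' @param intervals data frame with at least \code{frame_start},
#'   \code{frame_end}, \code{label}.
#' @param path file path.
#' @return \code{write_intervals} the path, invisibly;
#'   \code{read_intervals} a data frame.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(all(c("frame_start", "frame_end", "label") %in%
                names(intervals)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame intervals: 0-based, half-open [frame_start, frame_end)",
             con)
  df <- as.data.frame(intervals)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    rows <- vapply(seq_len(nrow(df)), function(i) {
      paste(vapply(seq_along(df), function(j) {
        if (num[j]) sprintf("%.17g", df[i, j]) else as.character(df[i, j])
      }, ""), collapse = "\t")
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("interval file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(data.frame(frame_start = integer(), frame_end = integer(),
                      label = character()))
  }
  stopifnot(all(c("frame_start", "frame_end", "label") %in% names(df)))
  if (any(df$frame_end <= df$frame_start)) {
    stop("invalid interval: frame_end must exceed frame_start")
  }
  for (lab in unique(df$label)) {
    sub <- df[df$label == lab, , drop = FALSE]
    sub <- sub[order(sub$frame_start), , drop = FALSE]
    if (nrow(sub) > 1 &&
        any(sub$frame_start[-1] < sub$frame_end[-nrow(sub)])) {
      stop(sprintf("overlapping '%s' intervals", lab))
    }
  }
  df$frame_start <- as.integer(df$frame_start)
  df$frame_end <- as.integer(df$frame_end)
  df
}

#' Write a report as JSON
#'
#' Drops non-scalar members (maps, detection objects) and serialises the
#' scalar summary with full precision.
#'
#' @param report named list.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  keep <- Filter(function(x) is.atomic(x) && length(x) <= 64, report)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
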