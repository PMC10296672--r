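# Shared fixtures: everything is generated in code at test time.

mucosa_eps <- function(f = 7.5e9) {
  complex_permittivity(dielectric_props(50, 6), f)
}

adenoma_eps <- function(f = 7.5e9) {
  complex_permittivity(dielectric_props(60, 8), f)
}

default_setup <- function() {
  geo <- array_geometry()
  list(geo = geo, sched = build_schedule(geo),
       k = wavenumber(mucosa_eps(geo$frequency)),
       grid = polar_grid())
}

# one-polyp scatterer table at radius r_mm / angle theta
polyp_scatterer <- function(theta, r_mm = 13, amplitude = 1) {
  chi <- dielectric_contrast(adenoma_eps(), mucosa_eps())
  data.frame(kind = "polyp", r_mm = r_mm, theta = theta, chi = chi,
             amplitude = amplitude)
}

# independent frame-by-frame labeller used as oracle for ground_truth:
# walks every frame and applies the priority rule directly
oracle_labels <- function(timeline) {
  lab <- rep("healthy", timeline$n_frames)
  for (f in 0:(timeline$n_frames - 1L)) {
    n_polyp <- 0L
    for (inc in timeline$inclusions) {
      if (f >= inc$frame_start && f < inc$frame_start + inc$frame_extent) {
        if (inc$kind == "polyp") n_polyp <- n_polyp + 1L
        else if (lab[f + 1L] == "healthy") lab[f + 1L] <- "stool"
      }
    }
    if (n_polyp == 1L) lab[f + 1L] <- "polyp"
    if (n_polyp >= 2L) lab[f + 1L] <- "cluster"
    for (ct in timeline$contacts) {
      if (f >= ct$frame_start && f < ct$frame_start + ct$frame_extent) {
        lab[f + 1L] <- "contact"
      }
    }
  }
  lab
}

intervals_to_labels <- function(track) {
  lab <- character(max(track$frame_end))
  for (i in seq_len(nrow(track))) {
    lab[(track$frame_start[i] + 1L):track$frame_end[i]] <- track$label[i]
  }
  lab
}
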