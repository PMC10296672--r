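# build a map/mask pair directly so threshold and run logic can be tested
# against hand-enumerated expectations
fake_map <- function(aggregate, n_theta = 64) {
  profiles <- matrix(0, length(aggregate), n_theta)
  profiles[, 1] <- aggregate
  structure(list(profiles = profiles, aggregate = aggregate,
                 grid = polar_grid(n_theta = n_theta)),
            class = "mw_contrast_map")
}
fake_mask <- function(valid) {
  structure(list(valid = valid, score = integer(length(valid)),
                 tau_chan = 0.5, m_min = 2L), class = "mw_validity")
}

test_that("threshold calibration is mu + k sigma over leading valid frames", {
  cfg <- detector_config(k_sigma = 5, calib_frames = 10)
  expect_equal(calibrate_threshold(fake_map(rep(0, 20)),
                                   fake_mask(rep(TRUE, 20)), cfg), 0)
  # constant aggregate: sigma = 0, threshold = the constant, any k
  expect_equal(calibrate_threshold(fake_map(rep(3.2, 20)),
                                   fake_mask(rep(TRUE, 20)), cfg), 3.2)
  # strictly increasing in k_sigma when sigma > 0
  a <- c(seq(0.9, 1.1, length.out = 20), rep(5, 5))
  ths <- vapply(c(1, 2, 5, 10), function(k) {
    calibrate_threshold(fake_map(a), fake_mask(rep(TRUE, 25)),
                        detector_config(k_sigma = k, calib_frames = 20))
  }, 0)
  expect_true(all(diff(ths) > 0))
  # invalid frames are skipped: calibration uses the first valid 10
  mu_skip <- calibrate_threshold(
    fake_map(c(100, rep(1, 24))), fake_mask(c(FALSE, rep(TRUE, 24))), cfg)
  expect_equal(mu_skip, 1)
  expect_error(calibrate_threshold(fake_map(rep(1, 5)),
                                   fake_mask(rep(TRUE, 5)), cfg),
               "too few valid")
})

test_that("run extraction matches a frame-enumeration bridging oracle", {
  cfg <- detector_config(gap_bridge = 3)
  n <- 200
  # nothing above threshold
  r <- find_runs(fake_map(rep(0, n)), fake_mask(rep(TRUE, n)), 1, cfg)
  expect_equal(nrow(r), 0)
  # frames 100..130 above threshold: single run [100, 131)
  a <- rep(0, n)
  a[101:131] <- 2
  r <- find_runs(fake_map(a), fake_mask(rep(TRUE, n)), 1, cfg)
  expect_equal(r, data.frame(frame_start = 100L, frame_end = 131L))
  # gap of 2 frames (111, 112) bridged with gap_bridge = 3
  a <- rep(0, n)
  a[101:111] <- 2 # frames 100..110
  a[114:121] <- 2 # frames 113..120
  r <- find_runs(fake_map(a), fake_mask(rep(TRUE, n)), 1, cfg)
  expect_equal(r, data.frame(frame_start = 100L, frame_end = 121L))
  # gap wider than the bridge splits the run
  r0 <- find_runs(fake_map(a), fake_mask(rep(TRUE, n)), 1,
                  detector_config(gap_bridge = 1))
  expect_equal(nrow(r0), 2)
  # invalid frames cannot start or end a run
  a <- rep(0, n)
  a[51:70] <- 2
  mask <- rep(TRUE, n)
  mask[c(51, 52, 69, 70)] <- FALSE # frames 50,51,68,69 invalid
  r <- find_runs(fake_map(a), fake_mask(mask), 1, cfg)
  expect_equal(r, data.frame(frame_start = 52L, frame_end = 68L))
})

test_that("run-width classification separates polyps from stool", {
  cfg <- detector_config(L_min = 10)
  map <- fake_map(rep(2, 60))
  runs <- data.frame(frame_start = c(0L, 30L, 40L),
                     frame_end = c(20L, 33L, 50L)) # lengths 20, 3, 10
  ev <- classify_runs(runs, map, cfg)
  expect_equal(ev$label, c("polyp", "stool", "polyp")) # L_min inclusive
  expect_equal(ev$frame_start, runs$frame_start)
  expect_true(all(ev$frame_end > ev$frame_start))
})

test_that("alert events carry the angular peak of the run", {
  grid <- polar_grid()
  profiles <- matrix(0, 30, grid$n_theta)
  profiles[10:20, 40] <- 3 # bright at angular bin 40
  map <- structure(list(profiles = profiles,
                        aggregate = apply(profiles, 1, max), grid = grid),
                   class = "mw_contrast_map")
  ev <- classify_runs(data.frame(frame_start = 9L, frame_end = 20L), map,
                      detector_config())
  expect_equal(ev$theta_peak, grid$theta_centers[40])
  expect_equal(ev$peak_contrast, 3)
})

test_that("healthy streams raise no alerts end to end", {
  st <- simulate_stream(scene_timeline(150), noise_rel = 0, seed = 3)
  det <- detect(st)
  expect_equal(nrow(det$events), 0)
  # with noise at the study level: no polyp alert either
  st <- simulate_stream(scene_timeline(200), noise_rel = 1e-3, seed = 3)
  det <- detect(st)
  expect_equal(sum(det$events$label == "polyp"), 0)
})

test_that("an isolated polyp yields one overlapping polyp alert", {
  tl <- scene_timeline(
    200, inclusions = list(inclusion("polyp", 2.1, frame_start = 120,
                                     frame_extent = 20)))
  st <- simulate_stream(tl, seed = 6)
  det <- detect(st)
  pol <- det$events[det$events$label == "polyp", ]
  expect_equal(nrow(pol), 1)
  expect_true(pol$frame_start < 140 && pol$frame_end > 120) # overlaps truth
  # the alert points at the right angle
  expect_lt(abs(((pol$theta_peak - 2.1 + pi) %% (2 * pi)) - pi),
            2 * 2 * pi / 64)
})

test_that("short stool inclusions alert as stool, never polyp", {
  tl <- scene_timeline(
    200, inclusions = list(inclusion("stool", 0.8, frame_start = 100,
                                     frame_extent = 3)))
  st <- simulate_stream(tl, seed = 8)
  det <- detect(st)
  expect_equal(sum(det$events$label == "polyp"), 0)
  expect_equal(sum(det$events$label == "stool"), 1)
})

test_that("isolated polyps are detected across seeds, stool never misread", {
  set.seed(99)
  for (seed in 1:20) {
    th <- runif(2, 0, 2 * pi)
    tl <- scene_timeline(
      220,
      inclusions = list(
        inclusion("polyp", theta_center = th[1], frame_start = 100,
                  frame_extent = 18),
        inclusion("stool", theta_center = th[2], frame_start = 170,
                  frame_extent = 4)))
    st <- simulate_stream(tl, seed = seed)
    det <- detect(st)
    pol <- det$events[det$events$label == "polyp", ]
    expect_equal(nrow(pol), 1)
    expect_true(pol$frame_start < 118 && pol$frame_end > 100)
  }
})

test_that("detection is deterministic given the stream", {
  st <- simulate_stream(replica_sequence_timeline(4), seed = 4)
  d1 <- detect(st)
  d2 <- detect(st)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$map$profiles, d2$map$profiles)
  expect_identical(d1$threshold, d2$threshold)
})
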