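test_that("switching schedule has 3 pairs per transmitter, 24 in total", {
  sched <- build_schedule(array_geometry())
  expect_equal(nrow(sched), 24)
  expect_equal(as.integer(table(sched$tx)), rep(3L, 8))
  # modular adjacency for the first transmitter: adjacent, diagonal -1, +1
  expect_equal(sched$rx[sched$tx == 1], c(1L, 8L, 2L))
  expect_equal(sched$rx[sched$tx == 5], c(5L, 4L, 6L))
  # every receiver appears exactly 3 times across the schedule
  expect_equal(as.integer(table(sched$rx)), rep(3L, 8))
})

test_that("complex Hankel kernel matches independently computed references", {
  ref <- list( # frozen from an independent special-function implementation
    list(z = 0.5 + 0i, v = complex(real = 0.938469807240813,
                                   imaginary = 0.444518733506707)),
    list(z = 3 - 1i, v = complex(real = -0.070605349041851,
                                 imaginary = -0.146310219591307)),
    list(z = 10 - 0.5i, v = complex(real = -0.148098208224224,
                                    imaginary = -0.0374217950424395)),
    list(z = 25 - 4i, v = complex(real = 0.00156221579453697,
                                  imaginary = 0.00244540465091782)),
    list(z = 50 - 7i, v = complex(real = 4.43312036118137e-05,
                                  imaginary = 9.22613463583627e-05)))
  for (r in ref) {
    expect_equal(mwcolon:::hankel02(r$z), r$v, tolerance = 1e-10)
  }
  # series and asymptotic branches agree near the switch point
  z <- complex(real = seq(15.5, 16.5, by = 0.1), imaginary = -2)
  rel <- Mod(mwcolon:::h02_series(z) - mwcolon:::h02_asymptotic(z)) /
    Mod(mwcolon:::h02_series(z))
  expect_lt(max(rel), 1e-8)
})

test_that("Green's function decays, is translation-invariant, and singular at r = 0", {
  k <- wavenumber(mucosa_eps())
  r <- seq(2, 40, by = 1)
  g <- mwcolon:::greens_dist(r, k)
  expect_true(all(diff(Mod(g)) < 0)) # lossy background: strict decay
  a <- c(3, 4)
  expect_equal(greens(a, a + c(5, 0), k), greens(a + c(-1, 7), a + c(4, 7), k))
  expect_error(greens(a, a, k), "singular")
})

test_that("Green's function approaches the r^(-1/2) cylindrical asymptote", {
  k_real <- wavenumber(complex_permittivity(dielectric_props(50, 0), 7.5e9))
  r_mm <- c(20, 30, 40)
  g <- mwcolon:::greens_dist(r_mm, k_real)
  asym <- (1 / 4) * sqrt(2 / (pi * Re(k_real) * r_mm * 1e-3))
  expect_equal(Mod(g), asym, tolerance = 0.05)
})

test_that("a centred scatterer illuminates all 24 channels equally", {
  s <- default_setup()
  sc <- polyp_scatterer(theta = 0)
  sc$r_mm <- 0 # exactly at the centre: equidistant from every antenna
  fr <- simulate_frame(s$geo, s$sched, sc, s$k)
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  scat <- fr$data - base
  expect_equal(Mod(scat), rep(Mod(scat)[1], 24), tolerance = 1e-9)
})

test_that("no scatterers and no noise reproduces the baseline exactly", {
  s <- default_setup()
  fr <- simulate_frame(s$geo, s$sched,
                       cross_section(scene_timeline(10), 0), s$k)
  expect_identical(fr$data, mwcolon:::baseline_channels(s$geo, s$sched, s$k))
  expect_true(fr$is_baseline)
})

test_that("rotating the scene by 45 degrees cyclically permutes the channels", {
  s <- default_setup()
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  set.seed(4)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    v0 <- simulate_frame(s$geo, s$sched, polyp_scatterer(th), s$k)$data - base
    v1 <- simulate_frame(s$geo, s$sched,
                         polyp_scatterer(th + 2 * pi / 8), s$k)$data - base
    # tx/rx indices shift by one antenna = 3 schedule rows
    expect_lt(max(Mod(v1 - v0[c(22:24, 1:21)])) / max(Mod(v0)), 1e-8)
  }
})

test_that("the Born forward model is linear in the scatterers", {
  s <- default_setup()
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  s1 <- polyp_scatterer(0.8)
  s2 <- polyp_scatterer(3.9, r_mm = 12.5)
  v1 <- simulate_frame(s$geo, s$sched, s1, s$k)$data - base
  v2 <- simulate_frame(s$geo, s$sched, s2, s$k)$data - base
  v12 <- simulate_frame(s$geo, s$sched, rbind(s1, s2), s$k)$data - base
  expect_lt(max(Mod(v12 - (v1 + v2))) / max(Mod(v12)), 1e-12)
})

test_that("scattered magnitude grows monotonically with |chi|", {
  s <- default_setup()
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  sc <- polyp_scatterer(1.1)
  mags <- vapply(c(0.5, 1, 2, 4), function(scale) {
    sc2 <- sc
    sc2$chi <- sc$chi * scale
    max(Mod(simulate_frame(s$geo, s$sched, sc2, s$k)$data - base))
  }, 0)
  expect_true(all(diff(mags) > 0))
})

test_that("a scatterer on an antenna is a singularity error", {
  s <- default_setup()
  sc <- polyp_scatterer(0)
  sc$r_mm <- s$geo$ring_radius # antenna 1 sits at (10, 0)
  expect_error(simulate_frame(s$geo, s$sched, sc, s$k), "antenna")
})

test_that("contact corruption scales only the affected channels", {
  s <- default_setup()
  fr <- simulate_frame(s$geo, s$sched, polyp_scatterer(2), s$k)
  # severity 1 with zero phase jitter: bit-identical frame
  ev <- contact_event(0, 1, affected_channels = c(1, 5), severity = 1)
  expect_identical(apply_contact(fr, ev, phase_jitter = 0)$data, fr$data)
  # severity 10 on channel 1: 10x magnitude there, others untouched
  ev10 <- contact_event(0, 1, affected_channels = 1, severity = 10)
  out <- apply_contact(fr, ev10)
  expect_equal(Mod(out$data[1]), 10 * Mod(fr$data[1]))
  expect_identical(out$data[-1], fr$data[-1])
})

test_that("stream simulation is reproducible and baseline-exact when empty", {
  tl <- scene_timeline(30)
  st <- simulate_stream(tl, noise_rel = 0, seed = 5)
  expect_equal(nrow(st$channels), 30)
  for (f in 1:30) expect_equal(st$channels[f, ], st$baseline)

  tl2 <- replica_sequence_timeline(3)
  a <- simulate_stream(tl2, seed = 9)
  b <- simulate_stream(tl2, seed = 9)
  expect_identical(a$channels, b$channels)
  expect_equal(nrow(a$channels), 600)
  c2 <- simulate_stream(tl2, seed = 10)
  expect_false(identical(a$channels, c2$channels))
})

test_that("stream simulation leaves the caller RNG state untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_stream(replica_sequence_timeline(1), seed = 2))
  expect_identical(.Random.seed, before)
})
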