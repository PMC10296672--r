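test_that("baseline estimation is exact on clean streams and windowed", {
  tl <- scene_timeline(80)
  st <- simulate_stream(tl, noise_rel = 0, seed = 1)
  expect_equal(estimate_baseline(st, 50), st$baseline)

  # polyps after the window do not touch the estimate
  tl2 <- scene_timeline(
    80, inclusions = list(inclusion("polyp", 1, frame_start = 60,
                                    frame_extent = 20)))
  st2 <- simulate_stream(tl2, noise_rel = 0, seed = 1)
  expect_equal(estimate_baseline(st2, 50), st2$baseline)

  expect_error(estimate_baseline(st, 81), "window")
})

test_that("baseline estimation error shrinks with the window", {
  tl <- scene_timeline(200)
  errs <- sapply(1:8, function(seed) {
    st <- simulate_stream(tl, noise_rel = 1e-3, seed = seed)
    c(w5 = max(Mod(estimate_baseline(st, 5) - st$baseline)),
      w50 = max(Mod(estimate_baseline(st, 50) - st$baseline)))
  })
  expect_lt(mean(errs["w50", ]), mean(errs["w5", ]))
})

test_that("a residual-free frame reconstructs to an all-zero image", {
  s <- default_setup()
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  img <- reconstruct_frame(base, base, s$geo, s$sched, s$grid, s$k)
  expect_true(all(unclass(img) == 0))
})

test_that("reconstruction is the adjoint: doubling contrast doubles pixels", {
  s <- default_setup()
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  sc <- polyp_scatterer(2.2)
  sc2 <- sc
  sc2$chi <- 2 * sc$chi
  i1 <- reconstruct_frame(simulate_frame(s$geo, s$sched, sc, s$k),
                          base, s$geo, s$sched, s$grid, s$k)
  i2 <- reconstruct_frame(simulate_frame(s$geo, s$sched, sc2, s$k),
                          base, s$geo, s$sched, s$grid, s$k)
  expect_equal(unclass(i2), 2 * unclass(i1), tolerance = 1e-12)
  expect_true(all(unclass(i1) >= 0))
})

test_that("a single scatterer localises to its angular bin", {
  s <- default_setup()
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  bin_w <- 2 * pi / s$grid$n_theta
  set.seed(31)
  for (i in 1:20) {
    th <- runif(1, 0, 2 * pi)
    fr <- simulate_frame(s$geo, s$sched, polyp_scatterer(th), s$k)
    prof <- aggregate_frame(
      reconstruct_frame(fr, base, s$geo, s$sched, s$grid, s$k))$profile
    th_hat <- s$grid$theta_centers[which.max(prof)]
    dth <- abs(((th_hat - th + pi) %% (2 * pi)) - pi)
    expect_lt(dth, 1.5 * bin_w) # within one bin of the true angle
  }
})

test_that("frame aggregation takes the radial and angular maxima", {
  s <- default_setup()
  img <- matrix(0, s$grid$n_r, s$grid$n_theta)
  zero <- structure(img, class = c("mw_image", "matrix"), grid = s$grid)
  agg <- aggregate_frame(zero)
  expect_equal(agg$profile, rep(0, s$grid$n_theta))
  expect_equal(agg$aggregate, 0)

  img[7, 13] <- 2.5
  one <- structure(img, class = c("mw_image", "matrix"), grid = s$grid)
  agg <- aggregate_frame(one)
  expect_equal(agg$profile[13], 2.5)
  expect_equal(sum(agg$profile > 0), 1)
  expect_equal(agg$aggregate, 2.5)

  # invariant under permutation of radial values within bins
  perm <- img[sample(nrow(img)), ]
  permuted <- structure(perm, class = c("mw_image", "matrix"), grid = s$grid)
  expect_equal(aggregate_frame(permuted)$profile, agg$profile)
})

test_that("the contrast map stacks per-frame aggregates consistently", {
  tl <- replica_sequence_timeline(2)
  st <- simulate_stream(tl, seed = 2)
  base <- estimate_baseline(st, 50)
  grid <- polar_grid()
  map <- build_contrast_map(st, base, grid)
  expect_equal(nrow(map$profiles), 600)
  expect_equal(ncol(map$profiles), grid$n_theta)
  expect_equal(map$aggregate, apply(map$profiles, 1, max))
  for (f in c(1, 300, 600)) {
    img <- reconstruct_frame(st$channels[f, ], base, st$geometry,
                             st$schedule, grid, st$k_bg)
    expect_equal(map$profiles[f, ], aggregate_frame(img)$profile,
                 tolerance = 1e-12)
  }
})

test_that("noise-free healthy streams give an exactly zero map", {
  tl <- scene_timeline(60)
  st <- simulate_stream(tl, noise_rel = 0, seed = 1)
  map <- build_contrast_map(st, estimate_baseline(st, 50), polar_grid())
  expect_true(all(map$profiles == 0))
  expect_true(all(map$aggregate == 0))
})

test_that("rotating the scene by 45 degrees shifts the profile by n_theta/8", {
  s <- default_setup()
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  th <- 1.3
  p0 <- aggregate_frame(reconstruct_frame(
    simulate_frame(s$geo, s$sched, polyp_scatterer(th), s$k),
    base, s$geo, s$sched, s$grid, s$k))$profile
  p1 <- aggregate_frame(reconstruct_frame(
    simulate_frame(s$geo, s$sched, polyp_scatterer(th + 2 * pi / 8), s$k),
    base, s$geo, s$sched, s$grid, s$k))$profile
  shift <- s$grid$n_theta / 8
  p0s <- p0[((seq_len(s$grid$n_theta) - 1 - shift) %% s$grid$n_theta) + 1]
  expect_lt(max(abs(p1 - p0s)) / max(p0), 1e-8)
})

test_that("the scalar aggregate grows monotonically with |chi|", {
  s <- default_setup()
  base <- mwcolon:::baseline_channels(s$geo, s$sched, s$k)
  sc <- polyp_scatterer(0.4)
  aggs <- vapply(c(0.25, 0.5, 1, 2), function(scale) {
    sc2 <- sc
    sc2$chi <- sc$chi * scale
    aggregate_frame(reconstruct_frame(
      simulate_frame(s$geo, s$sched, sc2, s$k),
      base, s$geo, s$sched, s$grid, s$k))$aggregate
  }, 0)
  expect_true(all(diff(aggs) > 0))
})
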