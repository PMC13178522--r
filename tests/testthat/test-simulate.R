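test_that("force rises sigmoidally and crosses half-maximum at the configured half-time", {
  cfg <- sim_config("tetanus", seed = 1)
  truth <- simulate_timecourse_truth(cfg)
  fr <- truth$frames
  plateau <- max(fr$force)
  rest <- fr$force[1]
  half <- rest + (plateau - rest) / 2
  # dense-grid oracle: where the configured closed form crosses half-maximum
  tg <- seq(0, 234, by = 0.1)
  dense <- truth_series(truth, "force", tg)
  t_half_dense <- tg[which(dense >= half)[1]]
  below <- max(fr$time_ms[fr$force < half & fr$time_ms < 150])
  above <- min(fr$time_ms[fr$force >= half])
  expect_lt(below, t_half_dense)
  expect_gte(above, t_half_dense)
  # the crossing stays close to the configured 72.3 ms half-time parameter
  expect_lt(abs(t_half_dense - 72.3), 10)
  # rest frames precede the first stimulus and carry resting force
  expect_true(all(fr$time_ms[1:2] < 0))
  expect_equal(fr$force[1:2], rep(0.65, 2))
})

test_that("rest == active configuration produces constant series", {
  ser <- list(force = list(active = 0.65), d10 = list(active = 39.10),
              S_M3 = list(active = 14.442, dev_fast = 0, kind = "sigmoid"),
              I_M3 = list(active = 1, dev_fast = 0, kind = "sigmoid"))
  truth <- simulate_timecourse_truth(sim_config("tetanus", seed = 1, series = ser))
  for (nm in c("force", "d10", "S_M3", "I_M3")) {
    expect_equal(diff(range(truth$frames[[nm]])), 0, info = nm)
  }
})

test_that("biphasic series minimum matches the dense closed-form oracle", {
  cfg <- sim_config("tetanus", seed = 1)
  truth <- simulate_timecourse_truth(cfg)
  tg <- seq(-20, 234, by = 0.1)
  dense <- truth_series(truth, "S_M3", tg)
  t_min_dense <- tg[which.min(dense)]
  fr <- truth$frames[truth$frames$time_ms <= 234, ]
  t_min_frames <- fr$time_ms[which.min(fr$S_M3)]
  expect_lt(abs(t_min_frames - t_min_dense), cfg$frame_pitch_ms)
  # the minimum exists: fast drop then slow rise
  expect_lt(min(dense), dense[1])
  expect_lt(min(dense), dense[length(dense)])
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config("tetanus", frame_pitch_ms = 0), "positive")
  expect_error(sim_config("tetanus", series = list(S_M3 = list(active = -1))),
               "positive")
  expect_error(sim_config("tetanus", series = list(nonsense = list(active = 1))),
               "unknown series")
})

test_that("rendering is bit-reproducible for a fixed seed", {
  cfg <- sparse_config(keep = c("eq", "m3"), seed = 99, n_frames = 8)
  truth <- simulate_timecourse_truth(cfg)
  f1 <- render_frame(truth, 2, small_geom())
  f2 <- render_frame(truth, 2, small_geom())
  expect_identical(f1$pixels, f2$pixels)
  # different frames use different substreams
  f3 <- render_frame(truth, 3, small_geom())
  expect_false(identical(f1$pixels, f3$pixels))
})

test_that("noise-free untilted frames are four-quadrant symmetric", {
  truth <- simulate_timecourse_truth(sparse_config(keep = c("eq", "m3", "ml1")))
  fr <- render_frame(truth, 1, small_geom(), noise = FALSE)
  px <- fr$pixels
  expect_equal(px, px[nrow(px):1, ], tolerance = 1e-10)
  expect_equal(px, px[, ncol(px):1], tolerance = 1e-10)
})

test_that("noise-free reflection counts integrate to amplitude x 2 pi x widths", {
  truth <- simulate_timecourse_truth(sparse_config(keep = "m3",
                                                   background_on = FALSE))
  geom <- small_geom()
  fr <- render_frame(truth, 1, geom, noise = FALSE)
  refl <- fibrediff:::reflection_table(truth, 1, "saxs")
  expected <- sum(refl$amplitude * 2 * pi * refl$sigma_axial * refl$sigma_radial)
  mid <- (nrow(fr$pixels) + 1) / 2
  upper <- fr$pixels[(mid + 1):nrow(fr$pixels), ]  # one axial half: one site set
  got <- sum(upper) * geom$scale_axial * geom$scale_radial
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("reflections outside the detector extent are skipped with a warning", {
  truth <- simulate_timecourse_truth(sparse_config(keep = c("eq", "m6")))
  tiny <- detector_geometry(301L, 151L, 2.5e-4, 4e-4, label = "tiny")
  expect_warning(render_frame(truth, 1, tiny, noise = FALSE),
                 "outside detector extent")
})

test_that("grating profiles place orders at k/period", {
  p <- generate_grating_profile(period = 100, reciprocal_scale = 2.5e-4,
                                n_orders = 11, noise_sd = 0)
  # noiseless peak maxima sit at k / period / scale pixels
  px_per_order <- (1 / 100) / 2.5e-4
  for (k in c(1, 5, 11)) {
    idx <- which.max(p$intensity[abs(p$q - k * px_per_order) < 10])
    near <- p$q[abs(p$q - k * px_per_order) < 10][idx]
    expect_equal(near, k * px_per_order, tolerance = 0.51)
  }
  expect_error(generate_grating_profile(n_orders = 1), "two")
  expect_error(generate_grating_profile(n_orders = 50), "extent")
})
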