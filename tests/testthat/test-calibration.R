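# Spatial calibration and sarcomere-length Bragg analysis.

test_that("grating calibration recovers the reciprocal scale", {
  scale_true <- 2.5e-4
  # jittered, noisy grating: recovery within 0.05%
  p <- generate_grating_profile(period = 100, reciprocal_scale = scale_true,
                                n_orders = 11, noise_sd = 0.01,
                                jitter_sd_px = 0.15, seed = 3)
  cal <- calibrate_from_grating(p, period = 100, max_order = 11)
  expect_equal(cal$reciprocal_scale, scale_true, tolerance = 5e-4)
  expect_equal(cal$n_orders, 11)
  # exact noiseless peaks: essentially zero residual and exact scale
  p0 <- generate_grating_profile(period = 100, reciprocal_scale = scale_true,
                                 n_orders = 11, noise_sd = 0)
  cal0 <- calibrate_from_grating(p0, period = 100)
  expect_equal(cal0$reciprocal_scale, scale_true, tolerance = 1e-5)
  expect_lt(cal0$residual_rms, 1e-6)
})

test_that("a beam-centre offset appears in the intercept, not the slope", {
  scale_true <- 2.5e-4
  p <- generate_grating_profile(period = 100, reciprocal_scale = scale_true,
                                n_orders = 11, noise_sd = 0, offset_px = 1.5)
  cal <- calibrate_from_grating(p, period = 100)
  expect_equal(cal$reciprocal_scale, scale_true, tolerance = 1e-4)
  expect_equal(cal$intercept, 1.5 * scale_true, tolerance = 0.05 * 1.5 * scale_true)
})

test_that("calibration halves fitted q when the grating period doubles", {
  scale_true <- 2.5e-4
  p200 <- generate_grating_profile(period = 200, reciprocal_scale = scale_true,
                                   n_orders = 8, noise_sd = 0)
  cal200 <- calibrate_from_grating(p200, period = 200, max_order = 8)
  # same pixel scale recovered with a different period; peak at fixed pixel
  # position maps to half the q when the period doubles
  expect_equal(cal200$reciprocal_scale, scale_true, tolerance = 1e-4)
  px <- 100
  q100 <- px * calibrate_from_grating(
    generate_grating_profile(100, scale_true, 11, 0), 100)$reciprocal_scale
  expect_equal(px * cal200$reciprocal_scale, q100, tolerance = 1e-3 * q100)
})

test_that("calibration demands at least three resolvable orders", {
  q <- 0:400
  y <- 50 + 1000 * exp(-(q - 40)^2 / 8) + 900 * exp(-(q - 80)^2 / 8)
  expect_error(calibrate_from_grating(new_profile(q, y)), "fewer than 3")
})

test_that("Bragg conversion and round trips are exact", {
  expect_equal(sl_from_order(5.761, 14), 14 / 5.761)
  expect_equal(sl_from_order(14 / 2430 * 1000, 14), 2.430, tolerance = 1e-12)
  expect_identical(sl_from_order(1 / 2.46, 1), 2.46)
  # round-trip identity for a range of orders
  for (n in c(1, 2, 14, 22)) expect_equal(sl_from_order(n / 2.43, n), 2.43)
  expect_error(sl_from_order(-1, 14), "positive")
  expect_error(sl_from_order(5, 0), "order")
})

test_that("the 14th-order reflection of a 2.43 um sarcomere sits in the 5-7 um^-1 window", {
  q14 <- 14 / 2.430
  expect_gt(q14, 5); expect_lt(q14, 7)
  expect_equal(q14, 5.761, tolerance = 1e-3)
})

test_that("sarcomere order fitting recovers truth and flags split populations", {
  q <- seq(5, 7, by = 0.005)
  y <- 4000 * exp(-(q - 5.761)^2 / (2 * 0.02^2))
  p <- new_profile(q, y, baseline_state = "subtracted", q_units = "um^-1")
  fit <- fit_sarcomere_order(p, c(5, 7), 14, sl_prior = 2.43)
  expect_equal(sl_from_order(fit$q_n, 14), 2.430, tolerance = 1e-4)
  expect_false(fit$low_confidence)
  # two overlapping populations: flagged low-confidence
  y2 <- y + 3500 * exp(-(q - 6.1)^2 / (2 * 0.02^2))
  fit2 <- fit_sarcomere_order(new_profile(q, y2, baseline_state = "subtracted",
                                          q_units = "um^-1"),
                              c(5, 7), 14, sl_prior = 2.43)
  expect_true(fit2$low_confidence)
})

test_that("sarcomere length from the 14th and 1st orders agrees across cameras", {
  truth <- simulate_timecourse_truth(sim_config("tetanus", seed = 21))
  f14 <- render_frame(truth, 1, geometry_usaxs_14(), camera = "usaxs14")
  sl14 <- measure_sarcomere(f14)$SL_um
  # higher orders fall off this very long camera by design
  f1 <- suppressWarnings(render_frame(truth, 1, geometry_usaxs_1(), camera = "usaxs1"))
  p1 <- integrate_frame(f1, "axial", c(0, 56e-5))
  p1 <- new_profile(p1$q * 1000, p1$intensity, q_units = "um^-1")
  p1 <- arc_hull_baseline(p1, smoothing = 0)$profile
  q1 <- fit_sarcomere_order(p1, c(0.25, 0.57), 1, sl_prior = 2.43)$q_n
  sl1 <- sl_from_order(q1, 1)
  expect_equal(sl14, 2.430, tolerance = 2e-3 / 2.43)
  expect_lt(abs(sl14 - sl1) / sl1, 0.003)
})
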