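# The reduction chain: centring, tilt correction, mirroring, integration,
# baseline subtraction.

test_that("centre and tilt are recovered from the equatorial 1,0 pair", {
  truth <- simulate_timecourse_truth(sparse_config(keep = c("eq", "m3")))
  geom <- small_geom(centre_offset_px = c(1.1, 2.3), tilt_deg = 0.8)
  fr <- render_frame(truth, 1, geom)
  cor <- find_centre_and_tilt(fr)
  expect_lt(max(abs(cor$correction$offset_px - c(1.1, 2.3))), 0.2)
  expect_lt(abs(cor$correction$tilt_deg - 0.8), 0.05)
  # corrected frame: residual estimates are small
  expect_lt(abs(cor$correction$residual_tilt_deg), 0.05)
  expect_lt(max(abs(cor$correction$residual_offset_px)), 0.15)
})

test_that("an already-centred noise-free frame gets an identity correction", {
  truth <- simulate_timecourse_truth(sparse_config(keep = c("eq", "m3")))
  fr <- render_frame(truth, 1, small_geom(), noise = FALSE)
  cor <- find_centre_and_tilt(fr)
  expect_lt(max(abs(cor$correction$offset_px)), 0.05)
  expect_lt(abs(cor$correction$tilt_deg), 0.01)
})

test_that("centring still converges when a tile gap hides one 1,0 reflection", {
  gap <- list(list(axis = "radial", q = c(0.022, 0.030), side = 1))
  truth <- simulate_timecourse_truth(sparse_config(keep = c("eq", "m3")))
  geom <- small_geom(centre_offset_px = c(0.6, -1.2), tile_gaps = gap)
  fr <- render_frame(truth, 1, geom)
  expect_true(any(fr$mask))
  cor <- find_centre_and_tilt(fr)
  expect_lt(max(abs(cor$correction$offset_px - c(0.6, -1.2))), 0.25)
})

test_that("centring fails informatively without a resolvable 1,0 pair", {
  truth <- simulate_timecourse_truth(sparse_config(keep = "m3"))
  fr <- render_frame(truth, 1, small_geom())
  expect_error(find_centre_and_tilt(fr), "1,0")
})

test_that("mirroring is an involution and preserves symmetric noise-free data", {
  truth <- simulate_timecourse_truth(sparse_config(keep = c("eq", "m3")))
  fr <- render_frame(truth, 1, small_geom(), noise = FALSE)
  m1 <- mirror_frame(fr, "both")
  expect_equal(m1$pixels, fr$pixels, tolerance = 1e-12)
  m2 <- mirror_frame(m1, "both")
  expect_equal(m2$pixels, m1$pixels, tolerance = 1e-12)
})

test_that("four-quadrant mirroring reduces per-pixel variance about fourfold", {
  truth <- simulate_timecourse_truth(sparse_config(keep = character(0)))
  expected <- render_frame(truth, 1, small_geom(), noise = FALSE)$pixels
  fr <- render_frame(truth, 1, small_geom())
  m <- mirror_frame(fr, "both")
  sel <- expected > 100  # bright background region, away from grid edges
  z_raw <- (fr$pixels[sel] - expected[sel]) / sqrt(expected[sel])
  z_mir <- (m$pixels[sel] - expected[sel]) / sqrt(expected[sel])
  ratio <- stats::var(z_raw) / stats::var(z_mir)
  expect_gt(ratio, 3.3)
  expect_lt(ratio, 4.7)
})

test_that("quadrant selection avoids masked tiles", {
  gap <- list(list(axis = "radial", q = c(0.038, 0.050), side = 1))
  truth <- simulate_timecourse_truth(sparse_config(keep = c("eq", "m3")))
  fr <- render_frame(truth, 1, small_geom(tile_gaps = gap))
  m <- mirror_frame(fr, "quadrants", quadrants = c("pm", "mm"))
  qr <- (seq_len(ncol(m$pixels)) - m$centre[2]) * m$scale_radial
  band <- abs(qr) >= 0.038 & abs(qr) <= 0.050
  expect_false(any(m$mask[, band]))
})

test_that("integration is linear and handles uniform frames exactly", {
  geom <- small_geom()
  px <- matrix(3, geom$n_axial, geom$n_radial)
  fr <- new_frame(px, geom)
  p <- integrate_frame(fr, "axial", c(0, 0.0038))
  qr <- (seq_len(geom$n_radial) - fr$centre[2]) * geom$scale_radial
  w <- sum(abs(qr) <= 0.0038)
  expect_true(all(p$intensity == 3 * w))
  # linearity
  fr5 <- new_frame(px * 5, geom)
  p5 <- integrate_frame(fr5, "axial", c(0, 0.0038))
  expect_equal(p5$intensity, 5 * p$intensity)
  # q strictly increasing
  expect_true(!is.unsorted(p$q, strictly = TRUE))
})

test_that("masked pixels are excluded with band renormalisation", {
  geom <- small_geom()
  px <- matrix(2, geom$n_axial, geom$n_radial)
  mask <- matrix(FALSE, geom$n_axial, geom$n_radial)
  mask[, 124:128] <- TRUE  # kill part of the meridional band
  fr <- new_frame(px, geom, mask = mask)
  p <- integrate_frame(fr, "axial", c(0, 0.0038))
  qr <- (seq_len(geom$n_radial) - fr$centre[2]) * geom$scale_radial
  w <- sum(abs(qr) <= 0.0038)
  expect_equal(unique(p$intensity), 2 * w)  # renormalised to full band
  expect_error(integrate_frame(fr, "axial", c(0, 0.0008)), "masked|no pixels")
})

test_that("arc-hull baseline recovers a Gaussian peak on a linear background", {
  q <- seq(0.01, 0.1, by = 2.5e-4)
  peak <- 800 * exp(-(q - 0.05)^2 / (2 * 0.002^2))
  y <- 200 - 1000 * q + peak
  p <- new_profile(q, y)
  res <- arc_hull_baseline(p, smoothing = 0)
  area_true <- 800 * 0.002 * sqrt(2 * pi)
  area_got <- sum(res$profile$intensity) * 2.5e-4
  expect_equal(area_got, area_true, tolerance = 0.02)
  # peak position unmoved by subtraction
  expect_lt(abs(res$profile$q[which.max(res$profile$intensity)] - 0.05), 2.5e-4 / 10 + 1e-9)
})

test_that("arc-hull baseline never exceeds the smoothed profile and handles degenerate input", {
  q <- seq(0, 1, length.out = 101)
  y <- exp(-2 * q) * 100  # convex, peak-free
  res <- arc_hull_baseline(new_profile(q, y), smoothing = 0)
  expect_true(all(res$baseline <= y + 1e-9))
  expect_true(all(res$profile$intensity >= -1e-9))
  expect_lt(max(res$profile$intensity), 0.02 * max(y))
  z <- arc_hull_baseline(new_profile(q, rep(0, 101)), smoothing = 2)
  expect_true(all(z$baseline == 0))
  expect_true(all(z$profile$intensity == 0))
  expect_error(arc_hull_baseline(new_profile(c(1, 2), c(1, 1))), "3 points")
})

test_that("baseline subtraction leaves synthetic peak centroids in place", {
  truth <- simulate_timecourse_truth(sparse_config(keep = "m3", seed = 5))
  fr <- render_frame(truth, 1, small_geom())
  p_raw <- integrate_frame(fr, "axial", c(0, 0.0038), q_range = c(0.05, 0.085))
  p_sub <- arc_hull_baseline(p_raw, smoothing = 2)$profile
  # compare the cluster centroid inside the M3 band, removing a local chord
  # from the raw profile so both centroids describe the same peak
  band <- p_raw$q >= 0.066 & p_raw$q <= 0.072
  chord <- approx(range(p_raw$q[band]),
                  p_raw$intensity[band][c(1, sum(band))],
                  xout = p_raw$q[band])$y
  w_raw <- pmax(p_raw$intensity[band] - chord, 0)
  c_raw <- sum(p_raw$q[band] * w_raw) / sum(w_raw)
  w_sub <- pmax(p_sub$intensity[band], 0)
  c_sub <- sum(p_sub$q[band] * w_sub) / sum(w_sub)
  # centroid of the cluster moves by well under a bin
  expect_lt(abs(c_raw - c_sub), 2.5e-4)
})
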