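# Constrained Gaussian decomposition: oracle equivalence on noise-free
# profiles, constraint exactness, scaling behaviour.

q_grid <- seq(0.012, 0.08, by = 2.5e-4)

test_that("equatorial fit is exact on noise-free hexagonal data", {
  d10 <- 39.10
  p <- gauss_profile(q_grid,
                     centres = c(1, sqrt(3), 2) / d10,
                     sigmas = c(0.0012, 0.0013, 0.0011),
                     amps = c(3000, 1740, 600))
  fit <- fit_equatorials(p)
  expect_equal(fit$d10, d10, tolerance = 1e-5)
  # lattice constraints hold exactly by construction
  expect_identical(fit$d11 * sqrt(3), fit$d10)
  expect_identical(fit$d20 * 2, fit$d10)
  expect_equal(fit$ratio_I11_I10,
               (1740 * 0.0013) / (3000 * 0.0012), tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-4 * 3000)
  # centres within 0.1%, areas within 1% of the generating components
  td <- tidy(fit)
  expect_equal(td$centre, c(1, sqrt(3), 2) / d10, tolerance = 1e-3)
  expect_equal(td$area, fibrediff:::gauss_area(c(3000, 1740, 600),
                                               c(0.0012, 0.0013, 0.0011)),
               tolerance = 1e-2)
})

test_that("equatorial fit scales linearly with profile amplitude", {
  d10 <- 39.7
  p1 <- gauss_profile(q_grid, c(1, sqrt(3), 2) / d10,
                      rep(0.0012, 3), c(1000, 1360, 300))
  p7 <- new_profile(p1$q, p1$intensity * 7, baseline_state = "subtracted")
  f1 <- fit_equatorials(p1)
  f7 <- fit_equatorials(p7)
  expect_equal(f7$I10 / f1$I10, 7, tolerance = 1e-6)
  expect_equal(f7$I11 / f1$I11, 7, tolerance = 1e-6)
  expect_equal(f7$d10, f1$d10, tolerance = 1e-8)
  expect_equal(f7$ratio_I11_I10, f1$ratio_I11_I10, tolerance = 1e-6)
})

test_that("equatorial fit rejects spacings outside the sanity window", {
  p <- gauss_profile(q_grid, c(1, sqrt(3), 2) / 52, rep(0.0012, 3),
                     c(1000, 500, 100))
  expect_error(fit_equatorials(p), "sanity|cover")
})

mk_m3_profile <- function(S = 14.442, I = 1, base = 700, noise = 0) {
  sp <- fibrediff:::m3_subpeaks()
  centres <- 1 / (S + sp$delta)
  amps <- base * sp$w * I
  sat_c <- c(0.0621, 0.0632, 0.0656, 0.0667, 1 / 15.52)
  sat_a <- c(25, 25, 25, 25, 60)
  q <- seq(0.058, 0.078, by = 2.5e-4)
  y <- rep(0, length(q))
  for (k in seq_along(centres)) y <- y + amps[k] * exp(-(q - centres[k])^2 / (2 * 5e-4^2))
  for (k in seq_along(sat_c)) y <- y + sat_a[k] * exp(-(q - sat_c[k])^2 / (2 * 5e-4^2))
  if (noise > 0) y <- y + rnorm(length(q), 0, noise)
  new_profile(q, y, baseline_state = "subtracted")
}

test_that("M3 cluster decomposition recovers the weighted spacing and obeys the sum rule", {
  p <- mk_m3_profile(S = 14.442)
  fit <- fit_interference_cluster(p, "M3", radial_width = 0.004)
  expect_equal(fit$spacing, 14.442, tolerance = 0.0005)
  main <- fit$components[fit$components$in_total, ]
  # sum rule: total intensity == sum of main component areas x radial width
  expect_identical(fit$total_intensity, sum(main$area) * 0.004)
  # weighted spacing bounded by component spacings
  expect_gte(fit$spacing, min(main$d))
  expect_lte(fit$spacing, max(main$d))
  # sub-peak labels ordered by spacing: LA largest d
  expect_gt(main$d[main$label == "M3-LA"], main$d[main$label == "M3-MA"])
  expect_gt(main$d[main$label == "M3-MA"], main$d[main$label == "M3-HA"])
  # satellites excluded from the totals
  expect_false(any(fit$components$in_total[fit$components$label %in%
                                             c("M3L", "X1", "X2", "X3", "X4")]))
})

test_that("M3 decomposition tracks an activated (shifted) cluster", {
  p <- mk_m3_profile(S = 14.558, I = 0.87)
  fit <- fit_interference_cluster(p, "M3", radial_width = 0.004)
  expect_equal(fit$spacing, 14.558, tolerance = 0.004)
})

test_that("M6 cluster recovers spacing within a hundredth of a nanometre", {
  sp <- fibrediff:::m6_subpeaks()
  S <- 7.230
  q <- seq(0.128, 0.145, by = 2.5e-4)
  y <- rep(0, length(q))
  for (k in 1:3) y <- y + 500 * sp$w[k] * exp(-(q - 1 / (S + sp$delta[k]))^2 / (2 * 5e-4^2))
  y <- y + 40 * exp(-(q - 1 / 7.62)^2 / (2 * 5e-4^2))
  p <- new_profile(q, y, baseline_state = "subtracted")
  fit <- fit_interference_cluster(p, "M6")
  expect_equal(fit$spacing, 7.230, tolerance = 0.002)
  # without a radial width the total is the plain component-area sum
  expect_identical(fit$total_intensity, sum(fit$components$area[fit$components$in_total]))
})

test_that("a single-component cluster collapses gracefully", {
  q <- seq(0.128, 0.145, by = 2.5e-4)
  y <- 400 * exp(-(q - 1 / 7.23)^2 / (2 * 5e-4^2))
  fit <- fit_interference_cluster(new_profile(q, y, baseline_state = "subtracted"), "M6")
  # spacing equals the single peak spacing; satellites carry ~no area
  expect_equal(fit$spacing, 7.23, tolerance = 0.002)
  main <- fit$components[fit$components$in_total, ]
  expect_gt(max(main$area), 100 * sum(fit$components$area[!fit$components$in_total]) - 1e-9)
})

test_that("cross-meridional width returns the narrow component", {
  q <- seq(2e-4, 0.06, by = 4e-4)
  y <- 1000 * exp(-q^2 / (2 * 0.004^2)) + 300 * exp(-q^2 / (2 * 0.02^2)) + 50
  w <- cross_meridional_width(new_profile(q, y))
  expect_equal(as.numeric(w), 0.004, tolerance = 0.05 * 0.004)
  expect_false(attr(w, "ambiguous"))
  # degenerate single-Gaussian input triggers the warning path
  y1 <- 800 * exp(-q^2 / (2 * 0.008^2))
  expect_warning(w1 <- cross_meridional_width(new_profile(q, y1)),
                 "indistinguishable|negligible")
  expect_equal(as.numeric(w1), 0.008, tolerance = 0.2 * 0.008)
})

test_that("doubling the radial width doubles the corrected intensity", {
  p <- mk_m3_profile()
  f1 <- fit_interference_cluster(p, "M3", radial_width = 0.004)
  f2 <- fit_interference_cluster(p, "M3", radial_width = 0.008)
  expect_equal(f2$total_intensity / f1$total_intensity, 2, tolerance = 1e-9)
})

test_that("band intensity integrates with partial-bin weighting", {
  q <- seq(0, 1, by = 0.01)
  y <- as.numeric(q >= 0.2 & q <= 0.4)  # unit-height rectangle-ish
  p <- new_profile(q, y, baseline_state = "subtracted")
  expect_equal(band_intensity(p, c(0.25, 0.35)), 0.10, tolerance = 1e-9)
  # window edges between samples are interpolated
  expect_equal(band_intensity(p, c(0.255, 0.355)), 0.10, tolerance = 1e-9)
  expect_error(band_intensity(p, c(2, 3)), "outside")
})

test_that("AL6 deconvolution separates overlapping M7/M8 tails", {
  q <- seq(0.150, 0.198, by = 2.5e-4)
  mk <- function(aal6) {
    y <- aal6 * exp(-(q - 0.1694)^2 / (2 * 8e-4^2)) +
      0.5 * aal6 * exp(-(q - 0.1617)^2 / (2 * 8e-4^2)) +
      0.5 * aal6 * exp(-(q - 0.1848)^2 / (2 * 8e-4^2))
    new_profile(q, y, baseline_state = "subtracted")
  }
  profs <- lapply(c(100, 120, 159), mk)
  out <- deconvolve_al6(profs)
  a_true <- fibrediff:::gauss_area(c(100, 120, 159), 8e-4)
  expect_equal(out$I_AL6, a_true, tolerance = 0.05)
  # rest -> peak ratio recovered
  expect_equal(out$I_AL6[3] / out$I_AL6[1], 1.59, tolerance = 0.05)
  # with M7 = M8 = 0, the deconvolved area matches the plain band integral
  solo <- new_profile(q, 100 * exp(-(q - 0.168)^2 / (2 * 8e-4^2)),
                      baseline_state = "subtracted")
  out2 <- deconvolve_al6(list(solo, solo))
  expect_equal(out2$I_AL6[1], band_intensity(solo, c(0.160, 0.176)),
               tolerance = 0.02)
  # narrow mode is a plain 0.166-0.170 integral
  nar <- deconvolve_al6(solo, mode = "narrow")
  expect_equal(nar$I_AL6, band_intensity(solo, c(0.166, 0.170)), tolerance = 1e-9)
})

test_that("layer-line centroid spacing matches hand-computed oracles", {
  q <- seq(0.015, 0.04, by = 1e-4)
  p1 <- gauss_profile(q, 1 / 37.5, 8e-4, 100)
  expect_equal(layerline_centroid_spacing(p1), 37.5, tolerance = 0.02)
  # delta-like single bin
  y <- rep(0, length(q)); y[101] <- 5
  expect_equal(layerline_centroid_spacing(new_profile(q, y)), 1 / q[101],
               tolerance = 1e-9)
  # two equal peaks at 1/43 and 1/37.5: centroid is the mean of the centres,
  # so the spacing is 2/(1/43 + 1/37.5) = 40.06 nm
  p2 <- gauss_profile(q, c(1 / 43, 1 / 37.5), c(5e-4, 5e-4), c(80, 80))
  expect_equal(layerline_centroid_spacing(p2), 2 / (1 / 43 + 1 / 37.5),
               tolerance = 0.02)
  expect_error(layerline_centroid_spacing(new_profile(q, rep(0, length(q)))),
               "non-positive")
})
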