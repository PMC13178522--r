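# Time-course assembly: mass correction, normalisation, smoothing, QC,
# period averaging.

mk_tc <- function(n = 30, pitch = 10, t0 = -22, stim = seq(0, 234, length.out = 20),
                  I_M3 = NULL, force = NULL) {
  t <- t0 + (seq_len(n) - 1) * pitch
  tibble::tibble(
    frame = seq_len(n), time_ms = t,
    force = force %||% pmax(0.65, 106 * plogis((t - 72) / 20) * (t >= 0)),
    I_M3 = I_M3 %||% rep(2000, n),
    I_ML1 = rep(500, n),
    S_M3 = rep(14.442, n)
  ) |> new_timecourse(stimulus_times = stim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mass-in-beam correction divides intensities by the relative background", {
  tc <- mk_tc()
  bg <- 600 * (1 + 0.10 * plogis((tc$time_ms - 72) / 20) * (tc$time_ms >= 0))
  out <- mass_in_beam_correction(tc, bg)
  f <- bg / mean(bg[1:3])
  expect_equal(out$I_M3, tc$I_M3 / f)
  expect_equal(out$S_M3, tc$S_M3)  # spacings untouched
  expect_equal(max(out$mass_correction), max(f))
  expect_equal(max(f) - 1, 0.10, tolerance = 0.01)
})

test_that("sub-threshold background changes skip the correction with provenance", {
  tc <- mk_tc()
  bg <- 600 * (1 + 0.004 * sin(seq_len(nrow(tc))))
  out <- mass_in_beam_correction(tc, bg)
  expect_equal(out$I_M3, tc$I_M3)
  expect_true(any(grepl("skipped", attr(out, "corrections"))))
  expect_error(mass_in_beam_correction(tc, rep(-1, nrow(tc))), "positive")
})

test_that("rest normalisation fixes the pre-stimulus level at one and is scale invariant", {
  tr <- 1 - 0.48 * plogis((seq(-22, 268, by = 10) - 30) / 10)
  tc <- mk_tc(I_M3 = 2000 * tr)
  out <- normalize_to_rest(tc)
  expect_equal(mean(out$I_M3[attr(out, "rest_frames")]), 1)
  expect_equal(min(out$I_M3), 0.52, tolerance = 0.01)
  out7 <- normalize_to_rest(mk_tc(I_M3 = 7 * 2000 * tr))
  expect_equal(out7$I_M3, out$I_M3)
  # absolute observables stay absolute
  expect_equal(out$S_M3, tc$S_M3)
})

test_that("1:2:1 smoothing matches its kernel arithmetic", {
  expect_equal(smooth_121(rep(3, 10)), rep(3, 10))
  alt <- rep(c(1, -1), 5)
  expect_equal(smooth_121(alt)[2:9], rep(0, 8))
  imp <- c(0, 0, 4, 0, 0)
  expect_equal(smooth_121(imp), c(0, 1, 2, 1, 0))
  expect_error(smooth_121(c(1, 2)), "length")
})

test_that("QC excludes weakened, collagen-contaminated or degraded records", {
  rec <- tibble::tibble(
    record = 1:10,
    peak_force = c(100, 99, 97, 80, 96, 95, 94, 96, 93, 92),
    collagen = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    quality_degraded = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  out <- qc_exclude(rec)
  expect_equal(sum(out$qc_pass), 7)
  expect_false(out$qc_pass[4])  # 20% decline
  expect_true(grepl("declined", out$qc_reason[4]))
  expect_true(out$qc_pass[10])  # 8% decline, retained
  expect_error(qc_exclude(tibble::tibble(record = 1:2, peak_force = c(100, 10),
                                         collagen = c(TRUE, FALSE))),
               "all records")
})

test_that("period averages use 3-4 frames and recover configured levels", {
  t <- seq(-22, 608, by = 10)
  n <- length(t)
  ratio <- 0.58 + (1.36 - 0.58) * plogis((t - 61) / 18) * (t >= 0) *
    fibrediff:::relax_envelope(t, 1.7, 23)
  tc <- new_timecourse(
    tibble::tibble(frame = seq_len(n), time_ms = t,
                   force = 0.65 + 105 * plogis((t - 72) / 20) * (t >= 0) *
                     fibrediff:::relax_envelope(t, 1.7, 23),
                   ratio_I11_I10 = ratio),
    stimulus_times = seq(0, 234, length.out = 20))
  per <- period_averages(tc)
  expect_true(all(per$n_frames %in% 3:4))
  peak <- per[per$period == "peak force" & per$parameter == "ratio_I11_I10", ]
  expect_equal(peak$mean, 1.36, tolerance = 0.02)
  rest <- per[per$period == "rest" & per$parameter == "ratio_I11_I10", ]
  expect_equal(rest$mean, 0.58, tolerance = 1e-6)
})

test_that("correction and normalisation commute on intensity series", {
  tc <- mk_tc(I_M3 = 2000 * (1 + 0.3 * plogis((seq(-22, 268, 10) - 40) / 10)))
  bg <- 600 * (1 + 0.1 * plogis((tc$time_ms - 72) / 20))
  a <- normalize_to_rest(mass_in_beam_correction(tc, bg))
  b <- mass_in_beam_correction(normalize_to_rest(tc), bg)
  # commutes up to the (tiny) variation of the correction factor over the
  # rest frames used as the normalisation reference
  expect_equal(a$I_M3, b$I_M3, tolerance = 1e-4)
})

test_that("amplitudes are square roots of intensities (Jensen ordering over records)", {
  expect_equal(amplitude_from_intensity(0.52), 0.72, tolerance = 0.005)
  expect_equal(amplitude_from_intensity(1), 1)
  expect_equal(amplitude_from_intensity(0.25), 0.5)
  expect_error(amplitude_from_intensity(-0.1), "non-negative")
  # averaging sqrt(I) across records then squaring never exceeds mean(I)
  set.seed(42)
  for (i in 1:20) {
    I <- rgamma(25, shape = 4, rate = 4)
    expect_lte(mean(amplitude_from_intensity(I))^2, mean(I) + 1e-12)
  }
})

test_that("period means over simulated record ensembles recover truth within 2 SEM", {
  set.seed(7)
  n_rec <- 24
  peak_vals <- replicate(n_rec, {
    t <- seq(-22, 608, by = 10)
    y <- 1 - 0.45 * plogis((t - 50) / 15) * (t >= 0) + rnorm(length(t), 0, 0.04)
    force <- 0.65 + 105 * plogis((t - 72) / 20) * (t >= 0) *
      fibrediff:::relax_envelope(t, 1.7, 23)
    tc <- new_timecourse(tibble::tibble(frame = seq_along(t), time_ms = t,
                                        force = force, I_X = y),
                         stimulus_times = seq(0, 234, length.out = 20))
    per <- period_averages(tc)
    per$mean[per$period == "peak force" & per$parameter == "I_X"]
  })
  sem <- sd(peak_vals) / sqrt(n_rec)
  expect_lt(abs(mean(peak_vals) - 0.55), 2 * sem + 0.01)
})
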