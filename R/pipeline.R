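# End-to-end orchestration: raw frames -> profiles -> fits -> time courses
# -> kinetics, mirroring how a beamline series is analysed.

#' Reduce a raw small-angle frame
#'
#' Centring/tilt correction from the equatorial 1,0 pair followed by
#' four-quadrant mirroring.
#'
#' @param frame Raw `xfd_frame`.
#' @param mirror Mirroring mode passed to [mirror_frame()].
#' @return Centred, mirrored `xfd_frame`.
#' @export
reduce_frame <- function(frame, mirror = "both") {
  mirror_frame(find_centre_and_tilt(frame), mode = mirror)
}

#' Measure the standard observables on one reduced frame
#'
#' Integrates the standard regions of interest, subtracts arc-hull
#' baselines, and fits the equatorial triplet and the M3/M6 interference
#' clusters. Returns the per-frame observable row used to assemble time
#' courses, plus the AL6-band axial profile (deconvolved later at series
#' level) and the layer-line background integral used for the mass-in-beam
#' correction.
#'
#' @param frame A reduced (centred, mirrored) `xfd_frame`.
#' @param smoothing Arc-hull pre-smoothing (bins).
#' @param m3_init,m6_init Optional cluster fits from the previous frame,
#'   used to warm-start the per-frame decompositions.
#' @return A list: `row` (one-row tibble of observables), `al6_profile`,
#'   `profiles` (named list of subtracted profiles).
#' @export
measure_frame <- function(frame, smoothing = 2L, m3_init = NULL,
                          m6_init = NULL) {
  # meridional axial profile and cluster fits
  mer_raw <- integrate_frame(frame, "axial", roi_band("meridional_halfwidth"),
                             q_range = c(0.045, 0.160))
  mer <- arc_hull_baseline(mer_raw, smoothing = smoothing)$profile
  m3_rad <- integrate_frame(frame, "radial", roi_band("M3_axial"),
                            q_range = c(2e-4, 0.060))
  m3_width <- suppressWarnings(cross_meridional_width(m3_rad))
  m6_rad <- integrate_frame(frame, "radial", roi_band("M6_axial"),
                            q_range = c(2e-4, 0.060))
  m6_width <- suppressWarnings(cross_meridional_width(m6_rad))
  fit_m3 <- fit_interference_cluster(mer, "M3", radial_width = as.numeric(m3_width),
                                     init = m3_init, freeze_satellites = TRUE)
  fit_m6 <- fit_interference_cluster(mer, "M6", radial_width = as.numeric(m6_width),
                                     init = m6_init, freeze_satellites = TRUE)

  # equatorial profile and constrained triple-Gaussian fit
  eq_raw <- integrate_frame(frame, "radial", roi_band("equatorial_halfwidth"),
                            q_range = c(0.012, 0.080))
  eq <- arc_hull_baseline(eq_raw, smoothing = smoothing)$profile
  fit_eq <- fit_equatorials(eq)

  # ML1/AL1 layer-line axial distribution: baseline integral measures the
  # diffuse scatter (mass in beam); band integral 0.017-0.024 measures I_ML1
  ll_raw <- integrate_frame(frame, "axial", roi_band("layerline_radial"),
                            q_range = c(0.008, 0.060))
  ll <- arc_hull_baseline(ll_raw, smoothing = smoothing)
  bg_integral <- trapz_window(ll_raw$q, ll$baseline)
  I_ML1 <- band_intensity(ll$profile, "ML1_axial")

  # sampled layer-line spots: radial distribution of the first layer line,
  # integrated over the 1,0 and 1,1+2,0 equatorial-column bands
  z1_raw <- integrate_frame(frame, "radial", roi_band("ML1_axial_wide"),
                            q_range = c(0.012, 0.080))
  z1 <- arc_hull_baseline(z1_raw, smoothing = smoothing)$profile
  I_101 <- band_intensity(z1, "eq10_radial")
  I_1121 <- band_intensity(z1, "eq1120_radial")

  # AL6 band axial profile, deconvolved at series level
  al6_raw <- integrate_frame(frame, "axial", roi_band("AL6_radial"),
                             q_range = c(0.150, 0.198))
  al6 <- arc_hull_baseline(al6_raw, smoothing = smoothing)$profile

  row <- tibble(
    time_ms = frame$frame_time,
    d10 = fit_eq$d10, ratio_I11_I10 = fit_eq$ratio_I11_I10,
    I_10 = fit_eq$I10, I_11 = fit_eq$I11,
    I_M3 = fit_m3$total_intensity, S_M3 = fit_m3$spacing,
    I_M6 = fit_m6$total_intensity, S_M6 = fit_m6$spacing,
    I_ML1 = I_ML1, I_101 = I_101, I_1121 = I_1121,
    m3_width = as.numeric(m3_width), m6_width = as.numeric(m6_width),
    ll_background = bg_integral
  )
  list(row = row, al6_profile = al6, fit_m3 = fit_m3, fit_m6 = fit_m6,
       fit_eq = fit_eq,
       profiles = list(meridional = mer, equatorial = eq, layerline = ll$profile))
}

#' Measure sarcomere length from an ultra-small-angle frame
#'
#' Meridional integration (band half-width 0.00304 nm^-1), arc-hull
#' baseline, single-Gaussian fit of the stated order, Bragg conversion.
#'
#' @param frame Rendered ultra-small-angle `xfd_frame` (already centred:
#'   these cameras have no resolvable 1,0 pair, so the nominal centre is
#'   used, as when analysing camera-aligned beamline data).
#' @param order Sarcomere reflection order to fit.
#' @param window Acceptance window (um^-1).
#' @param sl_prior Prior sarcomere length (um).
#' @param smoothing Arc-hull pre-smoothing; 0 for the very-long-camera
#'   first-order data.
#' @return A list: `SL_um`, `q_n`, `low_confidence`.
#' @export
measure_sarcomere <- function(frame, order = 14L, window = c(5, 7),
                              sl_prior = 2.43, smoothing = 2L) {
  prof_raw <- integrate_frame(frame, "axial", c(0, 0.00304))
  # work in um^-1 for the sarcomere analysis
  prof_raw <- new_profile(prof_raw$q * 1000, prof_raw$intensity,
                          prof_raw$variance, roi = attr(prof_raw, "roi"),
                          q_units = "um^-1")
  prof <- arc_hull_baseline(prof_raw, smoothing = smoothing)$profile
  fit <- fit_sarcomere_order(prof, window, order, sl_prior)
  list(SL_um = sl_from_order(fit$q_n, order), q_n = fit$q_n,
       low_confidence = fit$low_confidence)
}

#' Simulate, render and analyse a full contraction series
#'
#' Runs the complete chain on synthetic data: ground-truth time courses,
#' per-frame rendering of the small-angle (and optionally ultra-small-angle)
#' cameras, centring/mirroring, integration, baseline subtraction, peak
#' fitting, AL6 series deconvolution with 1:2:1 smoothing, mass-in-beam
#' correction and rest normalisation.
#'
#' @param config An `xfd_sim_config`.
#' @param geometry Small-angle detector geometry.
#' @param sarcomere If `TRUE`, also render and analyse the 14th-order
#'   sarcomere camera per frame.
#' @param frames Frame indices to analyse (default: all).
#' @param noise If `FALSE`, analyse noise-free renderings (bias oracle).
#' @param progress Print per-frame progress.
#' @return A list of class `xfd_run`: `truth`, `timecourse` (corrected and
#'   rest-normalised), `timecourse_raw`, `al6` (deconvolution table).
#' @export
analyse_synthetic_series <- function(config,
                                     geometry = geometry_saxs(centre_offset_px = c(-0.8, 1.2),
                                                              tilt_deg = 0.3),
                                     sarcomere = TRUE,
                                     frames = NULL, noise = TRUE,
                                     progress = FALSE) {
  truth <- simulate_timecourse_truth(config)
  frames <- frames %||% seq_len(nrow(truth$frames))
  usaxs_geom <- geometry_usaxs_14()
  sl_prior <- 2.43
  m3_prev <- NULL
  m6_prev <- NULL
  rows <- vector("list", length(frames))
  al6_profiles <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fi <- frames[i]
    red <- reduce_frame(render_frame(truth, fi, geometry, camera = "saxs",
                                     noise = noise))
    meas <- measure_frame(red, m3_init = m3_prev, m6_init = m6_prev)
    m3_prev <- meas$fit_m3
    m6_prev <- meas$fit_m6
    row <- meas$row
    if (sarcomere) {
      us <- render_frame(truth, fi, usaxs_geom, camera = "usaxs14",
                         noise = noise)
      # the order-assignment prior tracks the previous frame, since the
      # sarcomeres shorten by several percent during force development
      sl <- tryCatch(measure_sarcomere(us, sl_prior = sl_prior),
                     error = function(e) list(SL_um = NA_real_))
      row$SL_um <- sl$SL_um
      if (is.finite(sl$SL_um)) sl_prior <- sl$SL_um
    }
    row$frame <- fi
    rows[[i]] <- row
    al6_profiles[[i]] <- meas$al6_profile
    if (progress) message("frame ", fi, " done")
  }
  tab <- bind_rows(rows)
  al6 <- deconvolve_al6(al6_profiles)
  tab$I_AL6 <- smooth_121(al6$I_AL6)
  tab$force <- truth$frames$force[tab$frame]
  tc_raw <- new_timecourse(tab[, c("frame", "time_ms", "force",
                                   setdiff(names(tab), c("frame", "time_ms", "force")))],
                           truth$stimulus_times)
  tc <- mass_in_beam_correction(tc_raw, tab$ll_background)
  tc <- normalize_to_rest(tc)
  structure(list(truth = truth, timecourse = tc, timecourse_raw = tc_raw,
                 al6 = al6),
            class = "xfd_run")
}

#' Kinetics summary table for a time course
#'
#' Fits the standard kinetics to each observable of a tetanus time course:
#' single-sigmoid activation half-times (biphasic observables get a double
#' sigmoid with fast/slow branch half-times), single-sigmoid relaxation
#' half-times referenced to the last stimulus, and the linear (slow) and
#' exponential (fast) relaxation rate constants.
#'
#' @param tc A rest-normalised `xfd_timecourse`.
#' @param observables Columns to fit.
#' @param biphasic Columns fitted with the double sigmoid on activation.
#' @param act_window,rel_window Activation/relaxation fit windows (ms).
#' @return Tibble: `parameter`, `t_half_act`, `t_half_fast`, `t_half_slow`,
#'   `t_half_rel`, `k_slow`, `k_fast`.
#' @export
kinetics_table <- function(tc,
                           observables = c("force", "ratio_I11_I10", "S_M6",
                                           "I_M3", "S_M3", "I_ML1", "I_1121"),
                           biphasic = c("I_M3", "S_M3"),
                           act_window = c(-26, 234), rel_window = c(234, 604)) {
  last_stim <- max(attr(tc, "stimulus_times"))
  rest_frames <- attr(tc, "rest_frames")
  rows <- lapply(observables, function(obs) {
    y <- tc[[obs]]
    t <- tc$time_ms
    rest <- mean(y[rest_frames])
    act <- tryCatch({
      if (obs %in% biphasic) fit_double_sigmoid(t, y, act_window)
      else fit_sigmoid(t, y, act_window)
    }, error = function(e) NULL)
    rel <- tryCatch(fit_sigmoid(t, y, rel_window, t_ref = last_stim),
                    error = function(e) NULL)
    ks <- tryCatch(slow_krel(t, y, rest), error = function(e) NA_real_)
    kf <- tryCatch(fast_krel(t, y, rest), error = function(e) NA_real_)
    tibble(
      parameter = obs,
      t_half_act = if (!is.null(act) && length(act$t_half) == 1) act$t_half else NA_real_,
      t_half_fast = if (!is.null(act) && length(act$t_half) == 2) act$t_half[["fast"]] else NA_real_,
      t_half_slow = if (!is.null(act) && length(act$t_half) == 2) act$t_half[["slow"]] else NA_real_,
      t_half_rel = if (!is.null(rel)) rel$t_half else NA_real_,
      k_slow = ks, k_fast = kf
    )
  })
  bind_rows(rows)
}

#' @export
print.xfd_run <- function(x, ...) {
  cat("<xfd_run> ", x$truth$config$protocol, ", ",
      nrow(x$timecourse), " frames analysed\n", sep = "")
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Thin orchestration over the module functions: simulate (synthetic mode)
#' or load frames, reduce, fit, assemble time courses, fit kinetics and
#' write versioned outputs (CSV tables, JSON manifest) to the output
#' directory. Re-running with the same configuration and seed reproduces
#' the outputs exactly.
#'
#' @param config A configuration list or path to a YAML file with fields
#'   `protocol`, `seed`, `n_frames` (optional), `out_dir`, and optional
#'   `geometry` (`offset_axial_px`, `offset_radial_px`, `tilt_deg`),
#'   `sarcomere`, `mechanics` (parameter block for [motor_mechanics()]).
#' @return Invisibly, the `xfd_run` augmented with `kinetics` and file
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (required in c("protocol", "seed", "out_dir")) {
    if (is.null(config[[required]]))
      abort(paste0("config is missing required field '", required, "'"))
  }
  if (!is.null(config$stimulus_times) && length(config$stimulus_times) == 0)
    abort("stimulus times must be non-empty")
  sc <- sim_config(protocol = config$protocol,
                   n_frames = config$n_frames,
                   seed = config$seed,
                   series = config$series %||% list())
  geo_cfg <- config$geometry %||% list()
  geometry <- geometry_saxs(
    centre_offset_px = c(geo_cfg$offset_axial_px %||% 0,
                         geo_cfg$offset_radial_px %||% 0),
    tilt_deg = geo_cfg$tilt_deg %||% 0
  )
  run <- analyse_synthetic_series(sc, geometry,
                                  sarcomere = config$sarcomere %||% FALSE,
                                  frames = config$frames)
  run$kinetics <- kinetics_table(run$timecourse)

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tc_path <- file.path(out_dir, "timecourse.csv")
  kin_path <- file.path(out_dir, "kinetics.csv")
  per_path <- file.path(out_dir, "period_summary.csv")
  readr::write_csv(as_tibble(run$timecourse), tc_path)
  readr::write_csv(run$kinetics, kin_path)
  periods <- tryCatch(period_averages(run$timecourse), error = function(e) NULL)
  if (!is.null(periods)) readr::write_csv(periods, per_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fibrediff")),
    seed = config$seed, protocol = config$protocol,
    n_frames = nrow(run$timecourse),
    corrections = attr(run$timecourse, "corrections"),
    outputs = basename(c(tc_path, kin_path,
                         if (!is.null(periods)) per_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  run$paths <- list(timecourse = tc_path, kinetics = kin_path)
  invisible(run)
}
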