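#' Construct a stimulus-aligned time course
#'
#' A time course is a tibble with one row per frame (`frame`, `time_ms`,
#' observable columns) carrying the stimulus times and the set of rest
#' (pre-stimulus) frames as attributes. Intensity observables are columns
#' whose names start with `I_` (plus derived `A_` amplitudes); spacings,
#' sarcomere length, lattice spacing and force are never rescaled.
#'
#' @param frames Tibble with `frame`, `time_ms` and observable columns.
#' @param stimulus_times Stimulus times (ms); must be non-empty.
#' @return A tibble of class `xfd_timecourse`.
#' @export
new_timecourse <- function(frames, stimulus_times) {
  stopifnot(all(c("frame", "time_ms") %in% names(frames)))
  if (length(stimulus_times) == 0) abort("stimulus times must be non-empty")
  rest <- which(frames$time_ms < min(stimulus_times))
  if (length(rest) < 2) abort("need at least 2 pre-stimulus rest frames")
  out <- as_tibble(frames)
  class(out) <- c("xfd_timecourse", class(out))
  attr(out, "stimulus_times") <- stimulus_times
  attr(out, "rest_frames") <- rest
  attr(out, "corrections") <- character()
  out
}

tc_attrs <- function(tc) {
  list(stimulus_times = attr(tc, "stimulus_times"),
       rest_frames = attr(tc, "rest_frames"),
       corrections = attr(tc, "corrections") %||% character())
}

restore_tc <- function(out, tc, extra_correction = NULL) {
  class(out) <- unique(c("xfd_timecourse", class(out)))
  attr(out, "stimulus_times") <- attr(tc, "stimulus_times")
  attr(out, "rest_frames") <- attr(tc, "rest_frames")
  attr(out, "corrections") <- c(attr(tc, "corrections") %||% character(),
                                extra_correction)
  out
}

# Intensity observables subject to mass correction and rest normalisation.
# The equatorial ratio I11/I10 is excluded: it is reported in absolute
# units and any frame-wise scaling cancels in the ratio.
intensity_cols <- function(tc) {
  grep("^I_", names(tc), value = TRUE)
}

#' Correct intensities for changes in muscle mass in the beam
#'
#' Divides every intensity series frame-wise by the relative change in the
#' diffuse background under the ML1/AL1 layer-line band (background of the
#' frame over the mean rest background). Spacings are untouched. When the
#' background never deviates by more than `threshold` from rest (as in a
#' twitch, where the correction would be below 1%), the correction is
#' skipped and that decision recorded.
#'
#' @param tc An `xfd_timecourse`.
#' @param background_series Per-frame background integral of the
#'   0.037-0.064 nm^-1 radial band.
#' @param threshold Skip threshold on the maximum relative deviation.
#' @return The corrected `xfd_timecourse` (correction factors in
#'   `$mass_correction`).
#' @export
mass_in_beam_correction <- function(tc, background_series, threshold = 0.01) {
  stopifnot(length(background_series) == nrow(tc))
  if (any(background_series <= 0)) abort("background must be positive")
  rest <- attr(tc, "rest_frames")
  factor <- background_series / mean(background_series[rest])
  if (max(abs(factor - 1)) < threshold) {
    out <- tc
    out$mass_correction <- 1
    return(restore_tc(out, tc, "mass-in-beam: skipped (<1% background change)"))
  }
  out <- tc
  for (col in intensity_cols(tc)) out[[col]] <- out[[col]] / factor
  out$mass_correction <- factor
  restore_tc(out, tc, sprintf("mass-in-beam: applied (max %.1f%%)",
                              100 * max(abs(factor - 1))))
}

#' Normalise intensity series to their resting level
#'
#' Divides each intensity series by its mean over the pre-stimulus rest
#' frames, so rest = 1 by construction. Spacings, d10, sarcomere length and
#' force remain in absolute units.
#'
#' @param tc An `xfd_timecourse`.
#' @return The normalised `xfd_timecourse`.
#' @export
normalize_to_rest <- function(tc) {
  rest <- attr(tc, "rest_frames")
  out <- tc
  for (col in intensity_cols(tc)) {
    m <- mean(out[[col]][rest])
    if (!is.finite(m) || m == 0) abort(paste0("zero rest mean for ", col))
    out[[col]] <- out[[col]] / m
  }
  restore_tc(out, tc, "rest-normalised")
}

#' 1:2:1 smoothing
#'
#' Weighted moving average with kernel (1,2,1)/4; the endpoints use the
#' truncated, renormalised kernel (2,1)/3.
#'
#' @param series Numeric vector (length >= 3).
#' @return Smoothed vector of the same length.
#' @export
smooth_121 <- function(series) {
  n <- length(series)
  if (n < 3) abort("series must have length >= 3")
  out <- series
  out[2:(n - 1)] <- (series[1:(n - 2)] + 2 * series[2:(n - 1)] + series[3:n]) / 4
  out[1] <- (2 * series[1] + series[2]) / 3
  out[n] <- (series[n - 1] + 2 * series[n]) / 3
  out
}

#' Quality-control exclusion of contraction records
#'
#' Applies the record-level exclusion rules: peak force declined by more
#' than 15% from the first record, visible collagen-based reflections
#' (tendon in the beam), or substantial deterioration of pattern quality.
#'
#' @param records Tibble with columns `record`, `peak_force`, and logical
#'   `collagen` and `quality_degraded` flags.
#' @param force_decline_limit Maximum tolerated fractional decline.
#' @return The records tibble with `qc_pass` and `qc_reason` columns.
#' @export
qc_exclude <- function(records, force_decline_limit = 0.15) {
  stopifnot(all(c("record", "peak_force") %in% names(records)))
  ref <- records$peak_force[1]
  decline <- 1 - records$peak_force / ref
  get_flag <- function(nm) {
    if (nm %in% names(records)) records[[nm]] else rep(FALSE, nrow(records))
  }
  reasons <- pmap(list(decline, get_flag("collagen"), get_flag("quality_degraded")),
                  function(d, col, qd) {
    r <- character()
    if (d > force_decline_limit) r <- c(r, sprintf("force declined %.0f%%", 100 * d))
    if (isTRUE(col)) r <- c(r, "collagen reflections")
    if (isTRUE(qd)) r <- c(r, "pattern quality degraded")
    r
  })
  out <- records
  out$qc_pass <- lengths(reasons) == 0
  out$qc_reason <- vapply(reasons, function(r)
    if (length(r)) paste(r, collapse = "; ") else NA_character_, character(1))
  if (!any(out$qc_pass)) abort("all records excluded by quality control")
  out
}

#' Define averaging periods from the force trace
#'
#' Builds the standard averaging periods from force-trace landmarks: rest
#' (last pre-stimulus frames), peak force (frames around maximal force),
#' isometric relaxation (first frames after the last stimulus) and
#' mechanically relaxed (first frames after force returns below 5% of
#' peak). Each period holds 3-4 frames.
#'
#' @param tc An `xfd_timecourse` containing a `force` column.
#' @param n_frames Frames per period (3 or 4).
#' @return Tibble `period`, `frame`, `time_ms`.
#' @export
define_periods <- function(tc, n_frames = 3L) {
  if (!n_frames %in% c(3L, 4L)) abort("periods use 3 or 4 frames")
  stopifnot("force" %in% names(tc))
  rest <- tail(attr(tc, "rest_frames"), n_frames)
  last_stim <- max(attr(tc, "stimulus_times"))
  ipk <- which.max(tc$force)
  peak <- max(1, ipk - (n_frames - 1) %/% 2):(max(1, ipk - (n_frames - 1) %/% 2) + n_frames - 1)
  peak <- peak[peak <= nrow(tc)]
  iso <- which(tc$time_ms > last_stim)[seq_len(n_frames)]
  pk_force <- max(tc$force)
  rest_force <- mean(tc$force[rest])
  relaxed <- which(tc$time_ms > last_stim &
                     tc$force < rest_force + 0.05 * (pk_force - rest_force))
  relaxed <- head(relaxed, n_frames)
  per <- list(rest = rest, `peak force` = peak,
              `isometric relaxation` = iso,
              `mechanically relaxed` = relaxed)
  bind_rows(lapply(names(per), function(nm) {
    idx <- per[[nm]]
    if (!length(idx) || anyNA(idx)) return(NULL)
    tibble(period = nm, frame = tc$frame[idx], time_ms = tc$time_ms[idx])
  }))
}

#' Per-period means of every observable
#'
#' Averages 3-4 frames per period and reports mean and SD for each series.
#'
#' @param tc An `xfd_timecourse`.
#' @param periods Optional period table from [define_periods()].
#' @return Long tibble: `period`, `parameter`, `mean`, `sd`, `n_frames`.
#' @export
period_averages <- function(tc, periods = NULL) {
  periods <- periods %||% define_periods(tc)
  if (!nrow(periods)) abort("empty period definition")
  counts <- table(periods$period)
  if (any(counts < 3 | counts > 4))
    abort("each period must contain 3 or 4 frames")
  params <- setdiff(names(tc), c("frame", "time_ms", "mass_correction"))
  joined <- dplyr::inner_join(periods, as_tibble(tc), by = c("frame", "time_ms"))
  out <- joined |>
    tidyr::pivot_longer(all_of(params), names_to = "parameter",
                        values_to = "value") |>
    group_by(period, parameter) |>
    summarise(mean = mean(value), sd = sd(value), n_frames = dplyr::n(),
              .groups = "drop")
  out$period <- factor(out$period,
                       levels = c("rest", "early", "peak force",
                                  "isometric relaxation", "mechanically relaxed"))
  arrange(out, period, parameter)
}

#' Amplitude from a relative intensity
#'
#' Diffracted intensity scales with the square of the number of coherently
#' contributing diffractors, so relative amplitudes (proportional to
#' diffractor numbers) are the square roots of relative intensities.
#'
#' @param I_rel Relative intensity (>= 0).
#' @return `sqrt(I_rel)`.
#' @export
amplitude_from_intensity <- function(I_rel) {
  if (any(I_rel < 0)) abort("relative intensity must be non-negative")
  sqrt(I_rel)
}
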