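# broom-style tidiers for the fitted objects.

#' Tidy an equatorial fit
#'
#' @param x An `xfd_eqfit`.
#' @param ... Unused.
#' @return One row per Gaussian component: `label`, `centre`, `sigma`,
#'   `amplitude`, `area`, `spacing_nm`.
#' @export
tidy.xfd_eqfit <- function(x, ...) {
  mutate(x$components, spacing_nm = 1 / centre)
}

#' @rdname tidy.xfd_eqfit
#' @return `glance()`: one-row summary with `d10`, `ratio_I11_I10`,
#'   `residual_rms`, `n`.
#' @export
glance.xfd_eqfit <- function(x, ...) {
  tibble(d10 = x$d10, d11 = x$d11, d20 = x$d20,
         I10 = x$I10, I11 = x$I11, I20 = x$I20,
         ratio_I11_I10 = x$ratio_I11_I10,
         residual_rms = x$residual_rms, n = x$n)
}

#' Tidy a meridional interference-cluster fit
#'
#' @param x An `xfd_reflfit`.
#' @param ... Unused.
#' @return One row per fitted component, with `in_total` marking the
#'   LA/MA/HA sub-peaks that enter the reflection totals.
#' @export
tidy.xfd_reflfit <- function(x, ...) x$components

#' @rdname tidy.xfd_reflfit
#' @export
glance.xfd_reflfit <- function(x, ...) {
  tibble(family = x$family, spacing = x$spacing,
         total_intensity = x$total_intensity,
         radial_width = x$radial_width %||% NA_real_,
         la_dropped = x$la_dropped, residual_rms = x$residual_rms, n = x$n)
}

#' Tidy a kinetics fit
#'
#' @param x An `xfd_kinfit`.
#' @param ... Unused.
#' @return One row per fitted branch: `branch`, `t_half_ms`, `t_ref_ms`.
#' @export
tidy.xfd_kinfit <- function(x, ...) {
  branches <- if (length(x$t_half) == 2) c("fast", "slow") else "single"
  tibble(branch = branches, t_half_ms = unname(x$t_half), t_ref_ms = x$t_ref)
}

#' @rdname tidy.xfd_kinfit
#' @export
glance.xfd_kinfit <- function(x, ...) {
  tibble(kind = x$kind, model = x$model,
         n_branches = length(x$t_half),
         window_lo = x$window[1], window_hi = x$window[2],
         notes = if (length(x$notes)) paste(x$notes, collapse = "; ") else NA_character_)
}

#' Tidy a spatial calibration
#'
#' @param x An `xfd_calibration`.
#' @param ... Unused.
#' @return The per-order centroid table.
#' @export
tidy.xfd_calibration <- function(x, ...) x$centroids

#' @rdname tidy.xfd_calibration
#' @export
glance.xfd_calibration <- function(x, ...) {
  tibble(reciprocal_scale = x$reciprocal_scale, intercept = x$intercept,
         residual_rms = x$residual_rms, n_orders = x$n_orders,
         period = x$period, source = x$source)
}
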