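#' Spatial calibration from an etched grating
#'
#' Locates the diffraction orders of a grating of known periodicity in a 1D
#' profile recorded in pixel units, fits each peak centre, and regresses
#' pixel position against order index. The reciprocal scale is the increment
#' that maps the k-th peak to q = k/period; the regression intercept (in
#' q units) is reported as a beam-centring diagnostic.
#'
#' @param profile An `xfd_profile` with `q` in pixels (from a grating
#'   exposure integrated along the diffraction axis).
#' @param period Grating periodicity (nm).
#' @param max_order Highest order to use.
#' @param min_prominence Peak detection threshold as a fraction of the
#'   largest background-subtracted peak.
#' @return A list of class `xfd_calibration`: `reciprocal_scale` (nm^-1 per
#'   px), `intercept` (nm^-1), `residual_rms` (nm^-1), `n_orders`, `period`,
#'   `centroids` tibble, `source = "grating"`.
#' @export
calibrate_from_grating <- function(profile, period = 100, max_order = 11L,
                                   min_prominence = 0.02) {
  x <- profile$q
  y <- profile$intensity
  base <- median(y)
  ys <- boxcar_smooth(y - base, 1L)
  # local maxima above threshold
  thr <- min_prominence * max(ys)
  is_peak <- c(FALSE, ys[2:(length(ys) - 1)] > ys[1:(length(ys) - 2)] &
                 ys[2:(length(ys) - 1)] >= ys[3:length(ys)], FALSE) & ys > thr
  cand <- which(is_peak)
  # merge candidates closer than a few pixels (shoulders)
  if (length(cand) > 1) {
    keep <- c(TRUE, diff(cand) > 4)
    grp <- cumsum(keep)
    cand <- vapply(split(cand, grp), function(ix) ix[which.max(ys[ix])], numeric(1))
  }
  if (length(cand) < 3) abort("fewer than 3 grating orders detected")
  centroids <- vapply(cand, function(i0) {
    idx <- max(1, i0 - 5):min(length(x), i0 + 5)
    peak_centre_logparab(x[idx], y[idx], half_width = 5L)
  }, numeric(1))
  centroids <- sort(centroids)
  if (any(diff(centroids) <= 0)) abort("non-monotone grating centroids")
  spacing <- median(diff(centroids))
  k_first <- max(1L, round(centroids[1] / spacing))
  k <- k_first + seq_along(centroids) - 1L
  use <- k <= max_order
  if (sum(use) < 3) abort("fewer than 3 usable grating orders")
  k <- k[use]; centroids <- centroids[use]

  fit <- lm(centroids ~ k)
  slope_px <- coef(fit)[[2]]        # px per order
  intercept_px <- coef(fit)[[1]]
  scale <- (1 / period) / slope_px  # nm^-1 per px
  q_pred <- (centroids - intercept_px) * scale
  structure(
    list(reciprocal_scale = scale,
         intercept = intercept_px * scale,
         residual_rms = rms(q_pred - k / period),
         n_orders = length(k), period = period,
         centroids = tibble(order = k, position_px = centroids),
         source = "grating"),
    class = "xfd_calibration"
  )
}

#' @export
print.xfd_calibration <- function(x, ...) {
  cat(sprintf("<xfd_calibration> %.6g nm^-1/px from %d orders of a %g nm grating (rms %.2g)\n",
              x$reciprocal_scale, x$n_orders, x$period, x$residual_rms))
  invisible(x)
}

#' Fit the position of one sarcomere reflection order
#'
#' Fits a single Gaussian to a baseline-subtracted ultra-small-angle
#' meridional profile near the expected position of the given order
#' (computed from a prior sarcomere-length estimate) and verifies that the
#' centroid falls inside the stated window. If a second comparable peak sits
#' inside the window (multiple sarcomere populations, typical during
#' relaxation), the fit is flagged low-confidence.
#'
#' @param profile Baseline-subtracted `xfd_profile`, q in um^-1.
#' @param window Acceptance window for the centroid (um^-1), e.g. 5-7 for
#'   the 14th order or 0.25-0.57 for the 1st.
#' @param order Reflection order.
#' @param sl_prior Prior sarcomere length (um) used to localise the fit.
#' @return A list: `q_n` (um^-1), `order`, `low_confidence`, `sigma`,
#'   `amplitude`.
#' @export
fit_sarcomere_order <- function(profile, window, order, sl_prior = 2.4) {
  q <- profile$q; y <- profile$intensity
  q_exp <- order / sl_prior
  if (q_exp < window[1] || q_exp > window[2])
    abort("expected order position is outside the stated window")
  hw <- max(0.06 * q_exp, 0.08)
  sel <- q >= q_exp - hw & q <= q_exp + hw
  if (sum(sel) < 7) abort("profile does not resolve the expected order")
  qs <- q[sel]; ys <- y[sel]
  if (max(ys) <= 0) abort("no peak found in the order window")
  par <- c(a = max(ys), mu = qs[which.max(ys)], s = hw / 6, b = 0)
  fit <- lm_fit(par,
                lower = c(0, q_exp - hw, hw / 60, -Inf),
                upper = c(Inf, q_exp + hw, hw, Inf),
                function(p) gauss_peak(qs, p[["a"]], p[["mu"]], p[["s"]]) + p[["b"]] - ys)
  q_n <- fit$par[["mu"]]
  if (q_n < window[1] || q_n > window[2])
    abort("fitted sarcomere order outside the acceptance window")
  # competing population check inside the full window
  wsel <- q >= window[1] & q <= window[2]
  resid_other <- y[wsel] -
    gauss_peak(q[wsel], fit$par[["a"]], q_n, fit$par[["s"]]) - fit$par[["b"]]
  far <- abs(q[wsel] - q_n) > 3 * fit$par[["s"]]
  low_conf <- any(far) && max(resid_other[far]) > 0.5 * fit$par[["a"]]
  list(q_n = q_n, order = order, low_confidence = low_conf,
       sigma = fit$par[["s"]], amplitude = fit$par[["a"]])
}

#' Sarcomere length from a reflection order (Bragg)
#'
#' @param q_n Position of the n-th order sarcomere reflection (um^-1).
#' @param order Reflection order (>= 1).
#' @return Sarcomere length in um: `order / q_n`.
#' @export
sl_from_order <- function(q_n, order) {
  if (any(q_n <= 0)) abort("q_n must be positive")
  if (any(order < 1)) abort("order must be >= 1")
  order / q_n
}
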