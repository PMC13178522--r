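# Activation/relaxation kinetics of force and structural observables.

kin_result <- function(kind, t_half, t_ref, params, se = NULL, notes = character(),
                       window = NULL, model = "logistic") {
  structure(
    list(kind = kind, t_half = t_half, t_ref = t_ref, params = params,
         se = se, notes = notes, window = window, model = model),
    class = "xfd_kinfit"
  )
}

#' @export
print.xfd_kinfit <- function(x, ...) {
  cat("<xfd_kinfit> ", x$kind, ": t1/2 = ",
      paste(sprintf("%.1f", x$t_half), collapse = " / "),
      " ms (re t = ", x$t_ref, " ms)\n", sep = "")
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

kin_data <- function(time_ms, value, window) {
  sel <- time_ms >= window[1] & time_ms <= window[2]
  if (sum(sel) < 6) abort("need at least 6 points in the fit window")
  list(t = time_ms[sel], y = value[sel])
}

#' Fit a single sigmoidal transition
#'
#' Fits `y = y0 + a / (1 + exp(-(t - t_half)/tau))` by bounded least squares
#' and reports the half-time relative to `t_ref` (t = 0, the first stimulus,
#' for activation; the last stimulus for tetanus relaxation; t = 52.25 ms
#' for twitch relaxation).
#'
#' @param time_ms,value The series (ms, observable).
#' @param window Fit window `c(lo, hi)` in ms.
#' @param t_ref Reference time subtracted from the fitted half-time (ms).
#' @return An `xfd_kinfit` with `t_half` (ms re `t_ref`).
#' @export
fit_sigmoid <- function(time_ms, value, window = c(-26, 234), t_ref = 0) {
  d <- kin_data(time_ms, value, window)
  y0 <- mean(head(d$y, 2))
  a0 <- mean(tail(d$y, 2)) - y0
  if (abs(a0) < 1e-12 * max(abs(d$y), 1))
    abort("amplitude indistinguishable from zero")
  half_level <- y0 + a0 / 2
  cross <- which(sign(d$y - half_level) != sign(d$y[1] - half_level))[1]
  th0 <- if (is.na(cross)) mean(range(d$t)) else d$t[cross]
  span <- diff(range(d$t))
  par <- c(y0 = y0, a = a0, th = th0, tau = span / 10)
  fit <- lm_fit(par,
                lower = c(-Inf, -Inf, window[1] - span, span / 200),
                upper = c(Inf, Inf, window[2] + span, span),
                function(p) p[["y0"]] + p[["a"]] * plogis((d$t - p[["th"]]) / p[["tau"]]) - d$y)
  p <- fit$par
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) * fit$deviance / max(1, length(d$t) - 4)),
                 error = function(e) rep(NA_real_, 4))
  kin_result("sigmoid", t_half = p[["th"]] - t_ref, t_ref = t_ref,
             params = p, se = se, window = window)
}

#' Fit a biphasic (double-sigmoidal) transition
#'
#' Sum of two logistics with opposite-sign amplitudes, used for observables
#' with a fast falling phase followed by a slow rising phase (or vice
#' versa). The fast branch is constrained to precede the slow branch by at
#' least `min_separation` ms. If the second branch's amplitude collapses,
#' the fit falls back to a single sigmoid with a notice.
#'
#' @inheritParams fit_sigmoid
#' @param min_separation Minimum branch separation at initialisation (ms).
#' @return An `xfd_kinfit` whose `t_half` is `c(fast, slow)` (ms re
#'   `t_ref`), or a single-sigmoid `xfd_kinfit` on fallback.
#' @export
fit_double_sigmoid <- function(time_ms, value, window = c(-26, 234),
                               t_ref = 0, min_separation = 20) {
  d <- kin_data(time_ms, value, window)
  y0 <- mean(head(d$y, 2))
  yend <- mean(tail(d$y, 2))
  i_ext <- if (mean(d$y) < (y0 + yend) / 2) which.min(d$y) else which.max(d$y)
  y_ext <- d$y[i_ext]
  a1 <- y_ext - y0            # fast branch (towards the extremum)
  a2 <- yend - y_ext          # slow branch (back out of it)
  if (abs(a1) < 0.02 * max(abs(d$y - y0)) || sign(a1) == sign(a2) ||
      abs(a2) < 0.02 * max(abs(d$y - y0))) {
    fit <- fit_sigmoid(time_ms, value, window, t_ref)
    fit$notes <- c(fit$notes, "second branch amplitude ~0; single sigmoid fallback")
    return(fit)
  }
  th1 <- d$t[i_ext] / 2
  th2 <- max(th1 + min_separation, mean(d$t[d$t > d$t[i_ext]]))
  span <- diff(range(d$t))
  # parameterise slow half-time as th1 + exp-free positive gap to keep order
  par <- c(y0 = y0, a1 = a1, th1 = th1, tau1 = span / 25,
           a2 = a2, gap = th2 - th1, tau2 = span / 10)
  model <- function(p) {
    p[["y0"]] + p[["a1"]] * plogis((d$t - p[["th1"]]) / p[["tau1"]]) +
      p[["a2"]] * plogis((d$t - (p[["th1"]] + p[["gap"]])) / p[["tau2"]])
  }
  # opposite-sign amplitudes enforced through bounds chosen by branch signs
  lo_a1 <- if (a1 < 0) -Inf else 0; hi_a1 <- if (a1 < 0) 0 else Inf
  lo_a2 <- if (a2 < 0) -Inf else 0; hi_a2 <- if (a2 < 0) 0 else Inf
  fit <- lm_fit(par,
                lower = c(-Inf, lo_a1, window[1], span / 400, lo_a2,
                          min_separation, span / 400),
                upper = c(Inf, hi_a1, window[2], span, hi_a2, span, span),
                function(p) model(p) - d$y)
  p <- fit$par
  if (abs(p[["a2"]]) < 0.02 * abs(p[["a1"]])) {
    out <- fit_sigmoid(time_ms, value, window, t_ref)
    out$notes <- c(out$notes, "second branch amplitude ~0; single sigmoid fallback")
    return(out)
  }
  kin_result("double-sigmoid",
             t_half = c(fast = p[["th1"]] - t_ref,
                        slow = p[["th1"]] + p[["gap"]] - t_ref),
             t_ref = t_ref, params = p, window = window)
}

#' Rate constant of isometric (linear) relaxation
#'
#' Slope of the linear fit over the isometric-relaxation window, normalised
#' by the deviation from rest at the first frame after the last stimulus.
#'
#' @param time_ms,value The series.
#' @param rest_value Resting level of the observable.
#' @param window Linear-fit window (ms).
#' @return Rate constant in s^-1 (positive for decay towards rest).
#' @export
slow_krel <- function(time_ms, value, rest_value, window = c(244, 324)) {
  sel <- time_ms >= window[1] & time_ms <= window[2]
  if (sum(sel) < 3) abort("need at least 3 frames in the linear window")
  slope <- coef(lm(value[sel] ~ time_ms[sel]))[[2]]  # per ms
  v0 <- value[which(time_ms >= window[1])[1]]
  denom <- v0 - rest_value
  if (abs(denom) < 1e-12 * max(abs(value), 1))
    abort("deviation from rest at the window start is ~0")
  -slope * 1000 / denom
}

#' Rate constant of exponential relaxation
#'
#' Single-exponential decay towards the resting level fitted over the late
#' relaxation window.
#'
#' @inheritParams slow_krel
#' @param window Exponential-fit window (ms).
#' @return Rate constant in s^-1.
#' @export
fast_krel <- function(time_ms, value, rest_value, window = c(344, 604)) {
  sel <- time_ms >= window[1] & time_ms <= window[2]
  if (sum(sel) < 4) abort("need at least 4 frames in the exponential window")
  t <- time_ms[sel]; y <- value[sel]
  b0 <- y[1] - rest_value
  if (abs(b0) < 1e-12 * max(abs(value), 1)) return(0)
  par <- c(b = b0, k = 10)
  fit <- lm_fit(par, lower = c(-Inf, 0), upper = c(Inf, 1000),
                function(p) rest_value + p[["b"]] * exp(-p[["k"]] * (t - t[1]) / 1000) - y)
  fit$par[["k"]]
}
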