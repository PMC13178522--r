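#' Standard integration bands
#'
#' Named reciprocal-space bands used throughout the analysis, replicating
#' the regions used for rat soleus: meridional and equatorial integration
#' half-widths, the M3/M6 axial windows, layer-line radial and axial bands,
#' the equatorial-column radial bands for the sampled layer-line spots, the
#' AL6 deconvolution window and the sarcomere-order windows (um^-1).
#'
#' @return A tibble with columns `band`, `axis`, `lo`, `hi`, `units`.
#' @export
roi_bands <- function() {
  tibble(
    band = c("meridional_halfwidth", "equatorial_halfwidth",
             "M3_axial", "M6_axial",
             "layerline_radial", "ML1_axial",
             "ML1_axial_wide", "ML2_axial", "ML3_axial",
             "eq10_radial", "eq1120_radial",
             "AL6_axial", "AL6_radial", "AL6_axial_narrow",
             "SL1_centroid_axial",
             "sarc_14_axial_um", "sarc_1_axial_um"),
    axis = c("radial", "axial",
             "axial", "axial",
             "radial", "axial",
             "axial", "axial", "axial",
             "radial", "radial",
             "axial", "radial", "axial",
             "axial",
             "axial", "axial"),
    lo = c(0, 0,
           0.066, 0.135,
           0.037, 0.017,
           0.016, 0.041, 0.066,
           0.020, 0.037,
           0.166, 0.035, 0.166,
           0.0185,
           5, 0.25),
    hi = c(0.0038, 0.0036,
           0.072, 0.142,
           0.064, 0.024,
           0.034, 0.049, 0.072,
           0.035, 0.061,
           0.178, 0.060, 0.170,
           0.0355,
           7, 0.57),
    units = c(rep("nm^-1", 15), "um^-1", "um^-1")
  )
}

roi_band <- function(name) {
  b <- roi_bands()
  i <- match(name, b$band)
  if (is.na(i)) abort(paste0("unknown ROI band '", name, "'"))
  c(b$lo[i], b$hi[i])
}

# Gaussian centre of a projected peak; x in pixels. A bounded single
# Gaussian + offset fit, seeded from the windowed log-parabola; sub-0.1 px
# accuracy on the bright 1,0 reflections is needed for tilt correction.
project_peak_centre <- function(x, y, half_width = 6L) {
  seed <- peak_centre_logparab(x, y, half_width)
  b0 <- min(y)
  par <- c(a = max(y) - b0, mu = seed, s = half_width / 2, b = b0)
  fit <- tryCatch(
    lm_fit(par,
           lower = c(0, min(x), 0.5, -Inf),
           upper = c(Inf, max(x), diff(range(x)), Inf),
           function(p) gauss_peak(x, p[["a"]], p[["mu"]], p[["s"]]) + p[["b"]] - y),
    error = function(e) NULL)
  if (is.null(fit)) seed else fit$par[["mu"]]
}

# Locate the +/- 1,0 equatorial reflections in the radial direction.
# Returns the centre columns used on each side and the implied beam-centre
# column. When one 1,0 reflection is hidden (e.g. under a tile gap) the
# 1,1 reflection on that side substitutes, using the hexagonal ratio
# sqrt(3) between the 1,1 and 1,0 radii.
find_eq10_pair <- function(frame, centre, q_window = c(0.018, 0.035)) {
  qa <- (seq_len(nrow(frame$pixels)) - centre[1]) * frame$scale_axial
  band_rows <- which(abs(qa) <= 0.005)
  px <- frame$pixels[band_rows, , drop = FALSE]
  msk <- frame$mask[band_rows, , drop = FALSE]
  w <- colSums(!msk)
  prof <- ifelse(w > 0, colSums(px * !msk) / pmax(w, 1), 0)
  qr <- (seq_len(ncol(frame$pixels)) - centre[2]) * frame$scale_radial
  locate <- function(sgn, window) {
    sel <- which(sgn * qr >= window[1] & sgn * qr <= window[2] & w > 0)
    if (length(sel) < 5 || max(prof[sel]) <= 0) return(NA_real_)
    sub <- prof[sel]
    if ((max(sub) - median(sub)) < 3 * sqrt(max(median(sub), 1))) return(NA_real_)
    # demand an interior local maximum: a monotone background segment (e.g.
    # beside a masked tile) must not masquerade as a reflection
    imax <- which.max(sub)
    if (imax <= 2 || imax >= length(sub) - 1) return(NA_real_)
    project_peak_centre(sel, sub)
  }
  c10 <- vapply(c(-1, 1), locate, numeric(1), window = q_window)
  order_used <- c(1, 1)
  for (k in 1:2) {
    if (is.na(c10[k])) {
      c11 <- locate(c(-1, 1)[k], q_window * sqrt(3))
      if (!is.na(c11)) {
        c10[k] <- c11
        order_used[k] <- sqrt(3)
      }
    }
  }
  if (anyNA(c10)) return(list(cols = c10, centre_r = NA_real_))
  # solve for the beam centre from the two (possibly mixed-order) radii:
  # c_left = m - r1 * o1, c_right = m + r1 * o2 with r1 the 1,0 radius
  o <- order_used
  centre_r <- (o[1] * c10[2] + o[2] * c10[1]) / (o[1] + o[2])
  list(cols = c10, centre_r = centre_r)
}

# Axial (row) centroid of the intensity in a few columns around an
# equatorial reflection.
eq10_row_centre <- function(frame, centre, col_centre, col_hw = 5L, q_ax = 0.006) {
  cols <- max(1L, round(col_centre) - col_hw):min(ncol(frame$pixels), round(col_centre) + col_hw)
  qa <- (seq_len(nrow(frame$pixels)) - centre[1]) * frame$scale_axial
  rows <- which(abs(qa) <= q_ax)
  px <- frame$pixels[rows, cols, drop = FALSE]
  msk <- frame$mask[rows, cols, drop = FALSE]
  w <- rowSums(!msk)
  prof <- ifelse(w > 0, rowSums(px * !msk) / pmax(w, 1), 0)
  rows[1] - 1 + project_peak_centre(seq_along(rows), prof)
}

#' Centre and tilt-correct a detector frame using the equatorial 1,0 pair
#'
#' Finds the two 1,0 equatorial reflections on either side of the beam,
#' takes the beam centre as the midpoint of their fitted positions in both
#' detector directions and the pattern tilt from the line joining them, then
#' resamples the frame (bilinear, in reciprocal space) so the beam centre
#' sits exactly on the central pixel and the equator is exactly horizontal.
#' A second pass re-estimates the centre on the corrected frame. Masked
#' pixels propagate as masked.
#'
#' @param frame An `xfd_frame` containing a resolvable 1,0 pair.
#' @param q_window Radial search window for the 1,0 peak (nm^-1).
#' @return The corrected `xfd_frame`, with the applied offset (px) and tilt
#'   (degrees) recorded in `$correction`.
#' @export
find_centre_and_tilt <- function(frame, q_window = c(0.018, 0.035)) {
  stopifnot(inherits(frame, "xfd_frame"))
  centre0 <- frame$centre

  est <- function(fr, centre) {
    pair <- find_eq10_pair(fr, centre, q_window)
    if (is.na(pair$centre_r)) {
      abort("could not locate the 1,0 equatorial pair (signal-to-noise too low)")
    }
    cc <- pair$cols
    zz <- sapply(cc, function(cl) eq10_row_centre(fr, centre, cl))
    centre_a <- mean(zz)
    dqa <- (zz[2] - zz[1]) * fr$scale_axial
    dqr <- (cc[2] - cc[1]) * fr$scale_radial
    list(centre = c(centre_a, pair$centre_r), tilt = atan2(dqa, dqr) * 180 / pi)
  }

  e1 <- est(frame, centre0)
  corrected <- resample_frame(frame, e1$centre, e1$tilt)
  # second pass: residual centring on the corrected frame
  e2 <- est(corrected, corrected$centre)
  if (max(abs(e2$centre - corrected$centre)) > 0.15 || abs(e2$tilt) > 0.05) {
    corrected <- resample_frame(corrected, e2$centre, e2$tilt)
    e2 <- est(corrected, corrected$centre)
  }
  corrected$correction <- list(
    offset_px = e1$centre - centre0,
    tilt_deg = e1$tilt,
    residual_offset_px = e2$centre - (dim(frame$pixels) + 1) / 2,
    residual_tilt_deg = e2$tilt
  )
  corrected$provenance <- c(frame$provenance,
                            sprintf("centre+tilt[d=(%.2f,%.2f)px,t=%.3fdeg]",
                                    e1$centre[1] - centre0[1],
                                    e1$centre[2] - centre0[2], e1$tilt))
  corrected
}

# Resample a frame so that `centre` maps to the grid midpoint and the
# pattern is rotated by -tilt (degrees) in reciprocal space. Bilinear
# interpolation; any contribution from a masked pixel masks the output.
resample_frame <- function(frame, centre, tilt_deg) {
  na <- nrow(frame$pixels); nr <- ncol(frame$pixels)
  mid <- c((na + 1) / 2, (nr + 1) / 2)
  th <- tilt_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  sa <- frame$scale_axial; sr <- frame$scale_radial

  qa_out <- (seq_len(na) - mid[1]) * sa
  qr_out <- (seq_len(nr) - mid[2]) * sr
  QA <- matrix(qa_out, na, nr)
  QR <- matrix(qr_out, na, nr, byrow = TRUE)
  # sample the raw frame at the back-rotated coordinates so that the
  # corrected pattern has its equator exactly horizontal
  QA_src <- ct * QA + st * QR
  QR_src <- -st * QA + ct * QR
  I <- centre[1] + QA_src / sa
  J <- centre[2] + QR_src / sr

  i0 <- floor(I); j0 <- floor(J)
  fi <- I - i0; fj <- J - j0
  ok <- i0 >= 1 & i0 <= na - 1 & j0 >= 1 & j0 <= nr - 1
  vals <- matrix(0, na, nr)
  msk <- matrix(TRUE, na, nr)
  px <- frame$pixels
  mk <- frame$mask
  idx <- function(ii, jj) (jj - 1L) * na + ii
  w <- which(ok)
  i0w <- i0[w]; j0w <- j0[w]; fiw <- fi[w]; fjw <- fj[w]
  v00 <- px[idx(i0w, j0w)]; v10 <- px[idx(i0w + 1, j0w)]
  v01 <- px[idx(i0w, j0w + 1)]; v11 <- px[idx(i0w + 1, j0w + 1)]
  vals[w] <- v00 * (1 - fiw) * (1 - fjw) + v10 * fiw * (1 - fjw) +
    v01 * (1 - fiw) * fjw + v11 * fiw * fjw
  m00 <- mk[idx(i0w, j0w)]; m10 <- mk[idx(i0w + 1, j0w)]
  m01 <- mk[idx(i0w, j0w + 1)]; m11 <- mk[idx(i0w + 1, j0w + 1)]
  touched <- (m00 & (1 - fiw) * (1 - fjw) > 0.02) |
    (m10 & fiw * (1 - fjw) > 0.02) |
    (m01 & (1 - fiw) * fjw > 0.02) | (m11 & fiw * fjw > 0.02)
  msk[w] <- touched
  vals[msk] <- 0

  out <- frame
  out$pixels <- vals
  out$mask <- msk
  out$centre <- mid
  out$tilt <- 0
  out
}

#' Mirror a centred frame across the detector axes
#'
#' Averages the selected quadrants onto one another. Masked pixels are
#' excluded from the average with the weights renormalised; positions where
#' every contributing pixel is masked stay masked.
#'
#' @param frame A centred `xfd_frame` (beam centre on the middle pixel).
#' @param mode `"none"`, `"horizontal"` (average left/right),
#'   `"vertical"` (average up/down), `"both"`, or `"quadrants"`.
#' @param quadrants For `mode = "quadrants"`: subset of
#'   `c("pp","pm","mp","mm")` naming the (axial, radial) sign quadrants to
#'   use; the average of the selected quadrants is written to all four.
#' @return The mirrored `xfd_frame`.
#' @export
mirror_frame <- function(frame, mode = c("both", "horizontal", "vertical",
                                         "none", "quadrants"),
                         quadrants = c("pp", "pm", "mp", "mm")) {
  mode <- match.arg(mode)
  if (mode == "none") return(frame)
  na <- nrow(frame$pixels); nr <- ncol(frame$pixels)
  mid <- c((na + 1) / 2, (nr + 1) / 2)
  if (max(abs(frame$centre - mid)) > 1e-6)
    abort("frame must be centred before mirroring (run find_centre_and_tilt)")

  flips <- switch(mode,
    horizontal = list(c(FALSE, FALSE), c(FALSE, TRUE)),
    vertical = list(c(FALSE, FALSE), c(TRUE, FALSE)),
    both = list(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, FALSE), c(TRUE, TRUE)),
    quadrants = {
      sel <- match.arg(quadrants, c("pp", "pm", "mp", "mm"), several.ok = TRUE)
      # map each selected source quadrant onto the (+,+) orientation; the
      # symmetrised image is then written out to all quadrants
      lapply(sel, function(qd) c(substr(qd, 1, 1) == "m", substr(qd, 2, 2) == "m"))
    })

  out <- frame
  if (mode == "quadrants") {
    # fold the selected quadrants onto the (+,+) orientation, then reflect
    # the symmetrised quadrant back out to the whole grid
    half_a <- mid[1]:na; half_r <- mid[2]:nr
    fold_num <- matrix(0, length(half_a), length(half_r))
    fold_den <- matrix(0, length(half_a), length(half_r))
    for (f in flips) {
      px <- frame$pixels
      mk <- frame$mask
      if (f[1]) { px <- px[na:1, , drop = FALSE]; mk <- mk[na:1, , drop = FALSE] }
      if (f[2]) { px <- px[, nr:1, drop = FALSE]; mk <- mk[, nr:1, drop = FALSE] }
      fold_num <- fold_num + px[half_a, half_r] * !mk[half_a, half_r]
      fold_den <- fold_den + !mk[half_a, half_r]
    }
    quad <- ifelse(fold_den > 0, fold_num / fold_den, 0)
    quadm <- fold_den == 0
    ra <- abs(seq_len(na) - mid[1]) + 1
    rr <- abs(seq_len(nr) - mid[2]) + 1
    out$pixels <- quad[ra, rr, drop = FALSE]
    out$mask <- quadm[ra, rr, drop = FALSE]
  } else {
    num <- matrix(0, na, nr)
    den <- matrix(0, na, nr)
    for (f in flips) {
      px <- frame$pixels
      mk <- frame$mask
      if (f[1]) { px <- px[na:1, , drop = FALSE]; mk <- mk[na:1, , drop = FALSE] }
      if (f[2]) { px <- px[, nr:1, drop = FALSE]; mk <- mk[, nr:1, drop = FALSE] }
      num <- num + px * !mk
      den <- den + !mk
    }
    out$pixels <- ifelse(den > 0, num / den, 0)
    out$mask <- den == 0
  }
  out$provenance <- c(frame$provenance, paste0("mirror[", mode, "]"))
  out
}

#' Integrate a frame over a transverse band into a 1D profile
#'
#' Sums counts across the transverse band for each longitudinal bin on the
#' positive-q side of the pattern. Masked pixels are excluded and the band
#' width renormalised; Poisson variance is propagated with the same weights.
#'
#' @param frame A centred `xfd_frame`.
#' @param axis `"axial"` for a meridional profile (binned along the muscle
#'   axis, integrated across a radial band) or `"radial"` for an equatorial /
#'   layer-line radial profile (binned radially, integrated across an axial
#'   band).
#' @param band `c(lo, hi)` limits of |q| for the transverse integration
#'   (nm^-1); `lo = 0` gives the usual on-axis band of half-width `hi`.
#' @param q_range Optional `c(lo, hi)` to trim the longitudinal coordinate.
#' @return An `xfd_profile` (q in nm^-1).
#' @export
integrate_frame <- function(frame, axis = c("axial", "radial"), band,
                            q_range = NULL) {
  axis <- match.arg(axis)
  stopifnot(length(band) == 2, band[2] > band[1])
  na <- nrow(frame$pixels); nr <- ncol(frame$pixels)
  qa <- (seq_len(na) - frame$centre[1]) * frame$scale_axial
  qr <- (seq_len(nr) - frame$centre[2]) * frame$scale_radial

  if (axis == "axial") {
    trans <- which(abs(qr) >= band[1] & abs(qr) <= band[2])
    if (!length(trans)) abort("integration band selects no pixels")
    long_idx <- which(qa > 0)
    q <- qa[long_idx]
    px <- frame$pixels[long_idx, trans, drop = FALSE]
    mk <- frame$mask[long_idx, trans, drop = FALSE]
    n_tot <- length(trans)
    n_ok <- rowSums(!mk)
    if (all(n_ok == 0)) abort("integration band entirely masked")
    raw <- rowSums(px * !mk)
  } else {
    trans <- which(abs(qa) >= band[1] & abs(qa) <= band[2])
    if (!length(trans)) abort("integration band selects no pixels")
    long_idx <- which(qr > 0)
    q <- qr[long_idx]
    px <- frame$pixels[trans, long_idx, drop = FALSE]
    mk <- frame$mask[trans, long_idx, drop = FALSE]
    n_tot <- length(trans)
    n_ok <- colSums(!mk)
    if (all(n_ok == 0)) abort("integration band entirely masked")
    raw <- colSums(px * !mk)
  }
  scale <- ifelse(n_ok > 0, n_tot / n_ok, 0)
  intensity <- raw * scale
  variance <- raw * scale^2
  ord <- order(q)
  keep <- ord
  if (!is.null(q_range)) keep <- ord[q[ord] >= q_range[1] & q[ord] <= q_range[2]]
  new_profile(q[keep], intensity[keep], variance[keep],
              roi = list(axis = axis, band = band,
                         provenance = frame$provenance),
              baseline_state = "raw")
}

#' Arc-hull baseline estimation and subtraction
#'
#' Estimates the slowly varying background under a 1D profile as the lower
#' convex hull of the (optionally boxcar-smoothed) points, pushed below the
#' data by `depth` times the local noise scale, and subtracts it. With
#' `depth = 0` the baseline is the plain lower hull, so baseline <= smoothed
#' profile everywhere by construction. Negative residual intensities are
#' kept (not clipped) so band integrals stay unbiased.
#'
#' @param profile An `xfd_profile` with `baseline_state = "raw"`.
#' @param smoothing Boxcar half-width (bins) applied before hull fitting.
#' @param depth Baseline offset in units of the local noise scale.
#' @return A list with `profile` (baseline-subtracted `xfd_profile`) and
#'   `baseline` (numeric vector).
#' @export
arc_hull_baseline <- function(profile, smoothing = 2L, depth = 0) {
  if (nrow(profile) < 3) abort("need at least 3 points for a hull baseline")
  q <- profile$q
  y <- profile$intensity
  ysm <- boxcar_smooth(y, smoothing)
  hull <- lower_hull_idx(q, ysm)
  base <- approx(q[hull], ysm[hull], xout = q, rule = 2)$y
  if (depth > 0) {
    noise <- mad(diff(y)) / sqrt(2)
    base <- base - depth * noise
  }
  sub <- new_profile(q, y - base, profile$variance,
                     roi = attr(profile, "roi"),
                     baseline_state = "subtracted",
                     q_units = attr(profile, "q_units"))
  list(profile = sub, baseline = base)
}

#' Subtract a pre-recorded background frame
#'
#' Optional camera-background removal: subtracts a background exposure
#' pixel-wise (flooring at zero) and merges the masks.
#'
#' @param frame,background `xfd_frame`s of identical shape.
#' @return The corrected `xfd_frame`.
#' @export
subtract_background_frame <- function(frame, background) {
  stopifnot(identical(dim(frame$pixels), dim(background$pixels)))
  out <- frame
  out$pixels <- pmax(frame$pixels - background$pixels, 0)
  out$mask <- frame$mask | background$mask
  out$provenance <- c(frame$provenance, "camera-background")
  out
}
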