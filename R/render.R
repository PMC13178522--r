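#' Render a noisy 2D detector frame from simulated ground truth
#'
#' Expected counts are a smooth diffuse background (double exponential in
#' |q| with one axial anisotropy factor, scaled by the frame's relative
#' mass-in-beam factor) plus, for every reflection in the frame's parameter
#' table, separable 2D Gaussians placed four-quadrant symmetrically at
#' (+/- radial position, +/- 1/axial spacing). A non-zero geometry tilt
#' rotates the whole pattern about the true beam centre in reciprocal space;
#' tile-gap pixels are zeroed and masked. Observed counts are Poisson draws
#' from a per-frame substream derived deterministically from the master
#' seed, so rendering is bit-reproducible.
#'
#' The returned frame records the *nominal* beam centre (the grid midpoint),
#' not the true one: recovering the true centre and tilt is the job of
#' [find_centre_and_tilt()].
#'
#' @param truth An `xfd_truth`.
#' @param frame_index Frame number (row of `truth$frames`).
#' @param geometry An `xfd_geometry`; its `centre` and `tilt_deg` are the
#'   true pattern placement.
#' @param camera Which reflection set to render: the main small-angle
#'   pattern (`"saxs"`) or the ultra-small-angle sarcomere cameras.
#' @param noise If `FALSE`, return expected counts without Poisson noise.
#' @return An `xfd_frame`.
#' @export
render_frame <- function(truth, frame_index,
                         geometry = geometry_saxs(),
                         camera = c("saxs", "usaxs14", "usaxs1"),
                         noise = TRUE) {
  stopifnot(inherits(truth, "xfd_truth"))
  camera <- match.arg(camera)
  if (frame_index < 1 || frame_index > nrow(truth$frames))
    abort("frame_index out of range")
  fr <- truth$frames[frame_index, ]
  refl <- reflection_table(truth, frame_index, camera)

  na <- geometry$n_axial; nr <- geometry$n_radial
  sa <- geometry$scale_axial; sr <- geometry$scale_radial
  ctr <- geometry$centre
  theta <- geometry$tilt_deg * pi / 180
  ct <- cos(theta); st <- sin(theta)

  qa_vec <- (seq_len(na) - ctr[1]) * sa
  qr_vec <- (seq_len(nr) - ctr[2]) * sr

  # diffuse background, evaluated in the (possibly tilted) pattern frame
  QA <- matrix(qa_vec, na, nr)
  QR <- matrix(qr_vec, na, nr, byrow = TRUE)
  U <- ct * QA - st * QR   # axial coordinate in pattern frame
  V <- st * QA + ct * QR   # radial coordinate in pattern frame
  bgp <- truth$config$background
  Q <- sqrt(V^2 + (U / bgp$aniso)^2)
  lambda <- fr$bg_scale * (bgp$c1 * exp(-Q / bgp$l1) + bgp$c2 * exp(-Q / bgp$l2))
  rm(QA, QR, U, V, Q)

  # reflections: four-quadrant symmetric sites, each evaluated on a local
  # window around its (rotated) detector position
  qa_max <- max(abs(qa_vec)); qr_max <- max(abs(qr_vec))
  for (i in seq_len(nrow(refl))) {
    qa0 <- if (is.na(refl$d_axial[i])) 0 else 1 / refl$d_axial[i]
    qr0 <- refl$q_radial[i]
    sga <- refl$sigma_axial[i]; sgr <- refl$sigma_radial[i]
    # the mass-in-beam factor scales reflections as well as the diffuse
    # scatter; the mass correction divides it back out downstream
    amp <- refl$amplitude[i] * fr$bg_scale
    signs_a <- if (qa0 > 0) c(1, -1) else 1
    signs_r <- if (qr0 > 0) c(1, -1) else 1
    for (sa_sign in signs_a) for (sr_sign in signs_r) {
      pa <- sa_sign * qa0; pr <- sr_sign * qr0
      # detector-frame position of this site after tilt
      da <- ct * pa + st * pr
      dr <- -st * pa + ct * pr
      if (abs(da) > qa_max + 3 * sga || abs(dr) > qr_max + 3 * sgr) {
        warn(paste0("reflection ", refl$label[i], " outside detector extent; skipped"))
        next
      }
      hw_a <- 5 * sga + abs(st) * 5 * sgr
      hw_r <- 5 * sgr + abs(st) * 5 * sga
      rows <- which(qa_vec >= da - hw_a & qa_vec <= da + hw_a)
      cols <- which(qr_vec >= dr - hw_r & qr_vec <= dr + hw_r)
      if (!length(rows) || !length(cols)) next
      qa_w <- qa_vec[rows]; qr_w <- qr_vec[cols]
      U <- outer(qa_w, qr_w, function(a, r) ct * a - st * r)
      V <- outer(qa_w, qr_w, function(a, r) st * a + ct * r)
      lambda[rows, cols] <- lambda[rows, cols] +
        amp * exp(-((U - pa)^2) / (2 * sga^2) - ((V - pr)^2) / (2 * sgr^2))
    }
  }

  mask <- geometry_mask(geometry)
  lambda[mask] <- 0
  pixels <- if (noise) {
    with_local_seed(frame_seed(truth$seed, frame_index), {
      matrix(rpois(length(lambda), lambda), na, nr)
    })
  } else lambda

  new_frame(pixels, geometry, mask = mask,
            frame_time = fr$time_ms, exposure = truth$config$exposure,
            provenance = paste0("render[", camera, ",frame=", frame_index,
                                if (!noise) ",noise-free", "]"))
}

#' Simulate a calibration-grating profile
#'
#' Emulates the 1D integrated diffraction pattern of an etched grating of
#' known periodicity: Gaussian peaks at q = k/period for k = 1..n_orders
#' (amplitudes decaying geometrically with order) on a flat baseline, in
#' detector pixel units, with optional multiplicative noise and positional
#' jitter. Used to exercise [calibrate_from_grating()].
#'
#' @param period Grating periodicity (nm).
#' @param reciprocal_scale True reciprocal increment per pixel (nm^-1/px).
#' @param n_orders Number of diffraction orders (>= 2).
#' @param noise_sd Multiplicative noise fraction on each sample.
#' @param offset_px Pixel position of the zero-order (beam) relative to
#'   pixel 0, i.e. a beam-centre offset diagnostic.
#' @param jitter_sd_px Gaussian jitter applied to each peak position (px).
#' @param n_px Profile length (px).
#' @param peak_sigma_px Peak width (px).
#' @param seed RNG seed used when noise or jitter is requested.
#' @return An `xfd_profile` with `q` in pixel units.
#' @export
generate_grating_profile <- function(period = 100, reciprocal_scale = 2.5e-4,
                                     n_orders = 11L, noise_sd = 0,
                                     offset_px = 0, jitter_sd_px = 0,
                                     n_px = 600L, peak_sigma_px = 2.5,
                                     seed = 1L) {
  if (period <= 0) abort("period must be positive")
  if (n_orders < 2) abort("need at least two diffraction orders")
  px_per_order <- (1 / period) / reciprocal_scale
  if (offset_px + n_orders * px_per_order > n_px - 5 * peak_sigma_px)
    abort("n_orders exceeds the profile extent")
  x <- seq_len(n_px) - 1
  centres <- offset_px + seq_len(n_orders) * px_per_order
  make <- function(centres, noisy) {
    y <- rep(50, n_px)
    for (k in seq_len(n_orders)) {
      y <- y + gauss_peak(x, 1000 * 0.85^(k - 1), centres[k], peak_sigma_px)
    }
    if (noisy) y <- y * (1 + rnorm(n_px, 0, noise_sd))
    pmax(y, 0)
  }
  y <- if (noise_sd > 0 || jitter_sd_px > 0) {
    with_local_seed(seed, {
      if (jitter_sd_px > 0) centres <- centres + rnorm(n_orders, 0, jitter_sd_px)
      make(centres, noise_sd > 0)
    })
  } else make(centres, FALSE)
  new_profile(x, y, roi = list(axis = "grating", period = period),
              q_units = "px")
}
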