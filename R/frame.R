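#' Detector geometry descriptors
#'
#' A geometry describes the pixel grid of a detector and its mapping to
#' reciprocal space: the number of axial (meridional, along the muscle axis)
#' and radial (equatorial) pixels, the reciprocal-space increment per pixel in
#' each direction, the true beam centre (fractional pixel, 1-based), a pattern
#' tilt and optional dead-tile stripes. Grids are odd-sized so that a centred
#' frame has its beam centre exactly on the middle pixel, which makes
#' quadrant mirroring exact.
#'
#' `geometry_saxs()` emulates a camera recording the main small-angle region
#' (equatorials, M3/M6 clusters, layer lines out to the sixth actin layer
#' line at ~0.17 nm^-1). `geometry_usaxs_14()` emulates a long-camera
#' ultra-small-angle view of the high-order sarcomere reflections (axial
#' scale in nm^-1; 5-7 um^-1 falls well inside the grid), and
#' `geometry_usaxs_1()` a very long camera resolving the first few sarcomere
#' orders.
#'
#' @param n_axial,n_radial Odd grid dimensions (axial rows x radial columns).
#' @param scale_axial,scale_radial Reciprocal increment per pixel (nm^-1).
#' @param centre Fractional beam centre `c(axial, radial)`; defaults to the
#'   grid midpoint.
#' @param tilt_deg Pattern tilt in degrees (rotation of the diffraction
#'   pattern about the beam centre in reciprocal space).
#' @param tile_gaps List of dead stripes, each `list(axis = "axial"|"radial",
#'   q = c(lo, hi))` masking all pixels whose |q| along that axis falls in
#'   the band.
#' @param label Free-text geometry name carried into provenance.
#' @return An object of class `xfd_geometry`.
#' @export
detector_geometry <- function(n_axial, n_radial, scale_axial, scale_radial,
                              centre = NULL, tilt_deg = 0,
                              tile_gaps = list(), label = "custom") {
  stopifnot(n_axial %% 2L == 1L, n_radial %% 2L == 1L,
            scale_axial > 0, scale_radial > 0)
  if (is.null(centre)) centre <- c((n_axial + 1) / 2, (n_radial + 1) / 2)
  structure(
    list(n_axial = as.integer(n_axial), n_radial = as.integer(n_radial),
         scale_axial = scale_axial, scale_radial = scale_radial,
         centre = centre, tilt_deg = tilt_deg, tile_gaps = tile_gaps,
         label = label),
    class = "xfd_geometry"
  )
}

#' @rdname detector_geometry
#' @param centre_offset_px Offset of the true beam centre from the grid
#'   midpoint, `c(axial, radial)` in pixels.
#' @export
geometry_saxs <- function(centre_offset_px = c(0, 0), tilt_deg = 0,
                          tile_gaps = list()) {
  g <- detector_geometry(1601L, 701L, 2.5e-4, 4e-4,
                         tilt_deg = tilt_deg, tile_gaps = tile_gaps,
                         label = "saxs-8.26m")
  g$centre <- g$centre + centre_offset_px
  g
}

#' @rdname detector_geometry
#' @export
geometry_usaxs_14 <- function(centre_offset_px = c(0, 0)) {
  g <- detector_geometry(4001L, 151L, 5e-6, 5e-5, label = "usaxs-8.26m")
  g$centre <- g$centre + centre_offset_px
  g
}

#' @rdname detector_geometry
#' @export
geometry_usaxs_1 <- function(centre_offset_px = c(0, 0)) {
  g <- detector_geometry(1201L, 151L, 4e-6, 5e-5, label = "usaxs-31m")
  g$centre <- g$centre + centre_offset_px
  g
}

# Build the boolean dead-pixel mask implied by a geometry's tile gaps,
# evaluated about the *nominal* grid midpoint (tile gaps are a property of
# the detector, not of the diffraction pattern).
geometry_mask <- function(geom) {
  mask <- matrix(FALSE, geom$n_axial, geom$n_radial)
  if (length(geom$tile_gaps) == 0) return(mask)
  mid_a <- (geom$n_axial + 1) / 2
  mid_r <- (geom$n_radial + 1) / 2
  qa <- (seq_len(geom$n_axial) - mid_a) * geom$scale_axial
  qr <- (seq_len(geom$n_radial) - mid_r) * geom$scale_radial
  in_gap <- function(q, gap) {
    side <- gap$side %||% 0
    if (side == 0) abs(q) >= gap$q[1] & abs(q) <= gap$q[2]
    else side * q >= gap$q[1] & side * q <= gap$q[2]
  }
  for (gap in geom$tile_gaps) {
    if (gap$axis == "axial") mask[in_gap(qa, gap), ] <- TRUE
    else mask[, in_gap(qr, gap)] <- TRUE
  }
  mask
}

#' Construct a detector frame object
#'
#' A frame bundles a pixel count matrix with its dead-pixel mask and the
#' reciprocal-space metadata needed downstream. `centre` is the frame's
#' *current best estimate* of the beam centre (updated by
#' [find_centre_and_tilt()]); rows are axial (meridional) and columns radial
#' (equatorial).
#'
#' @param pixels Non-negative count matrix.
#' @param geom An `xfd_geometry`.
#' @param mask Logical matrix, `TRUE` = dead/gap pixel.
#' @param centre Current beam-centre estimate (fractional pixels).
#' @param frame_time Frame timestamp (ms, centre of integration window).
#' @param exposure Exposure per frame (ms).
#' @param provenance Character vector of processing steps applied.
#' @return An object of class `xfd_frame`.
#' @export
new_frame <- function(pixels, geom, mask = NULL, centre = NULL,
                      frame_time = NA_real_, exposure = NA_real_,
                      provenance = character()) {
  stopifnot(is.matrix(pixels), all(pixels >= 0 | is.na(pixels)))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  stopifnot(identical(dim(mask), dim(pixels)))
  if (is.null(centre)) centre <- c((nrow(pixels) + 1) / 2, (ncol(pixels) + 1) / 2)
  structure(
    list(pixels = pixels, mask = mask, centre = centre,
         scale_axial = geom$scale_axial, scale_radial = geom$scale_radial,
         tilt = 0, frame_time = frame_time, exposure = exposure,
         geometry_label = geom$label, provenance = provenance),
    class = "xfd_frame"
  )
}

#' @export
print.xfd_frame <- function(x, ...) {
  cat("<xfd_frame> ", nrow(x$pixels), "x", ncol(x$pixels),
      " [", x$geometry_label, "]\n", sep = "")
  cat("  centre: (", paste(round(x$centre, 2), collapse = ", "),
      ") px; scales: ", x$scale_axial, " x ", x$scale_radial,
      " nm^-1/px\n", sep = "")
  if (length(x$provenance)) cat("  steps:", paste(x$provenance, collapse = " > "), "\n")
  invisible(x)
}

#' @export
print.xfd_geometry <- function(x, ...) {
  cat("<xfd_geometry> ", x$label, ": ", x$n_axial, "x", x$n_radial,
      " px, ", x$scale_axial, "/", x$scale_radial, " nm^-1 per px\n", sep = "")
  invisible(x)
}

#' Construct a 1D intensity profile
#'
#' Profiles are tibbles with columns `q` (strictly increasing reciprocal
#' spacing), `intensity` and `variance`, plus attributes recording the region
#' of interest they came from and whether a baseline has been removed.
#'
#' @param q,intensity,variance Numeric vectors of equal length.
#' @param roi List describing the integration region (axis, band, mirroring).
#' @param baseline_state `"raw"` or `"subtracted"`.
#' @param q_units Units of `q` (`"nm^-1"`, `"um^-1"` or `"px"`).
#' @return A tibble of class `xfd_profile`.
#' @export
new_profile <- function(q, intensity, variance = NULL, roi = list(),
                        baseline_state = "raw", q_units = "nm^-1") {
  stopifnot(length(q) == length(intensity), !is.unsorted(q, strictly = TRUE),
            all(is.finite(intensity)))
  if (is.null(variance)) variance <- pmax(intensity, 0)
  out <- tibble(q = q, intensity = intensity, variance = variance)
  class(out) <- c("xfd_profile", class(out))
  attr(out, "roi") <- roi
  attr(out, "baseline_state") <- baseline_state
  attr(out, "q_units") <- q_units
  out
}

profile_meta <- function(profile) {
  list(roi = attr(profile, "roi"),
       baseline_state = attr(profile, "baseline_state") %||% "raw",
       q_units = attr(profile, "q_units") %||% "nm^-1")
}
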