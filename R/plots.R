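# ggplot2 visualisations of profiles, frames and time courses.

#' Plot a 1D diffraction profile
#'
#' @param object An `xfd_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xfd_profile <- function(object, ...) {
  meta <- profile_meta(object)
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(q, intensity)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = paste0("q (", meta$q_units, ")"),
      y = if (meta$baseline_state == "subtracted")
        "intensity (baseline subtracted)" else "intensity (counts)",
      title = paste0(meta$roi$axis %||% "profile",
                     if (!is.null(meta$roi$band))
                       sprintf(" | band %.4g-%.4g", meta$roi$band[1], meta$roi$band[2])
                     else "")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a detector frame as a log-scaled raster
#'
#' Downsamples large frames for display.
#'
#' @param object An `xfd_frame`.
#' @param max_px Maximum pixels per side after downsampling.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xfd_frame <- function(object, max_px = 400L, ...) {
  px <- object$pixels
  step_a <- max(1L, ceiling(nrow(px) / max_px))
  step_r <- max(1L, ceiling(ncol(px) / max_px))
  rows <- seq(1L, nrow(px), by = step_a)
  cols <- seq(1L, ncol(px), by = step_r)
  qa <- (rows - object$centre[1]) * object$scale_axial
  qr <- (cols - object$centre[2]) * object$scale_radial
  d <- expand.grid(q_axial = qa, q_radial = qr)
  d$counts <- as.vector(px[rows, cols])
  ggplot2::ggplot(d, ggplot2::aes(q_radial, q_axial, fill = log10(counts + 1))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 counts") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "radial q (nm^-1)", y = "axial q (nm^-1)") +
    ggplot2::theme_minimal()
}

#' Plot a stimulus-aligned time course
#'
#' Facets the selected observables against time, with stimulus onset/offset
#' marked.
#'
#' @param object An `xfd_timecourse`.
#' @param observables Columns to show (default: all measured series).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xfd_timecourse <- function(object, observables = NULL, ...) {
  skip <- c("frame", "time_ms", "mass_correction", "ll_background",
            "m3_width", "m6_width")
  observables <- observables %||% setdiff(names(object), skip)
  d <- tidyr::pivot_longer(as_tibble(object)[, c("time_ms", observables)],
                           -time_ms, names_to = "parameter")
  stim <- range(attr(object, "stimulus_times"))
  ggplot2::ggplot(d, ggplot2::aes(time_ms, value)) +
    ggplot2::geom_vline(xintercept = stim, linetype = 3, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time since first stimulus (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
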