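# Standard-format I/O: frames as TIFF, profiles/time courses as CSV with
# JSON sidecars, truth and calibration as JSON.

#' Write and read detector frames as TIFF
#'
#' Frames are stored as 32-bit float TIFF with the geometry metadata in a
#' JSON sidecar (`<path>.json`); the dead-pixel mask travels as a companion
#' boolean TIFF (`<path>.mask.tiff`) when present.
#'
#' @param frame An `xfd_frame`.
#' @param path Output path (`.tiff`).
#' @return `write_frame_tiff()`: the path, invisibly. `read_frame_tiff()`:
#'   an `xfd_frame`.
#' @export
write_frame_tiff <- function(frame, path) {
  scale <- max(frame$pixels, 1)
  tiff::writeTIFF(frame$pixels / scale, path, bits.per.sample = 32L)
  if (any(frame$mask))
    tiff::writeTIFF(frame$mask * 1, sub("\\.tiff?$", ".mask.tiff", path),
                    bits.per.sample = 8L)
  meta <- list(
    count_scale = scale,
    centre = frame$centre, scale_axial = frame$scale_axial,
    scale_radial = frame$scale_radial, tilt = frame$tilt,
    frame_time = frame$frame_time, exposure = frame$exposure,
    geometry_label = frame$geometry_label, provenance = frame$provenance
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * (meta$count_scale %||% 1)
  mask_path <- sub("\\.tiff?$", ".mask.tiff", path)
  mask <- if (file.exists(mask_path)) tiff::readTIFF(mask_path) > 0.5 else NULL
  geom <- detector_geometry(nrow(px), ncol(px), meta$scale_axial,
                            meta$scale_radial, label = meta$geometry_label)
  fr <- new_frame(px, geom, mask = mask, centre = meta$centre,
                  frame_time = meta$frame_time, exposure = meta$exposure,
                  provenance = meta$provenance)
  fr$tilt <- meta$tilt
  fr
}

#' Write a profile to CSV with a JSON ROI sidecar
#'
#' @param profile An `xfd_profile`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(as_tibble(profile), path)
  meta <- profile_meta(profile)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list()
  new_profile(d$q, d$intensity, d$variance,
              roi = meta$roi %||% list(),
              baseline_state = meta$baseline_state %||% "raw",
              q_units = meta$q_units %||% "nm^-1")
}

#' Write the force/stimulus trace of a simulated protocol
#'
#' CSV with columns `time_ms`, `force_kPa`, `stimulus_flag` (1 on frames
#' containing a stimulus).
#'
#' @param truth An `xfd_truth`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_force_trace <- function(truth, path) {
  fr <- truth$frames
  pitch <- stats::median(diff(fr$time_ms))
  stim <- vapply(fr$time_ms, function(t)
    any(truth$stimulus_times >= t - pitch / 2 &
          truth$stimulus_times < t + pitch / 2), logical(1))
  readr::write_csv(tibble(time_ms = fr$time_ms, force_kPa = fr$force,
                          stimulus_flag = as.integer(stim)), path)
  invisible(path)
}

#' Serialise simulation ground truth to JSON
#'
#' @param truth An `xfd_truth`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(frames = truth$frames, series = truth$config$series,
         stimulus_times = truth$stimulus_times, seed = truth$seed,
         protocol = truth$config$protocol),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
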