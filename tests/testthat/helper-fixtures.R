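# Shared fixtures: small geometries and reflection-sparse configurations so
# unit tests render quickly.

# Compact small-angle geometry covering the equatorials and the M3 cluster.
small_geom <- function(centre_offset_px = c(0, 0), tilt_deg = 0,
                       tile_gaps = list()) {
  g <- detector_geometry(701L, 251L, 2.5e-4, 4e-4, tilt_deg = tilt_deg,
                         tile_gaps = tile_gaps, label = "test-small")
  g$centre <- g$centre + centre_offset_px
  g
}

# Configuration whose renderer output contains only the components named in
# `keep` (amplitude overrides), optionally with the diffuse background off.
sparse_config <- function(keep = c("eq", "m3"), background_on = TRUE,
                          seed = 42L, ...) {
  all_amps <- c("eq", "m3", "m3l", "extras", "m6", "m6l", "m7", "m8",
                "ml1", "al1", "al6", "samp_101", "samp_111", "samp_201",
                "samp_102", "samp_112", "samp_202", "samp_103", "samp_113")
  zero <- setdiff(all_amps, keep)
  amps <- as.list(setNames(rep(0, length(zero)), zero))
  if (!"m3" %in% keep) amps$broad_frac <- 0
  bg <- if (background_on) list() else list(c1 = 0, c2 = 0)
  sim_config("tetanus", seed = seed, amps = amps, background = bg, ...)
}

# Direct Gaussian-mixture profile constructor (independent of the
# renderer) for peak-fit oracle tests.
gauss_profile <- function(q, centres, sigmas, amps, baseline = 0) {
  y <- rep(baseline, length(q))
  for (k in seq_along(centres)) {
    y <- y + amps[k] * exp(-(q - centres[k])^2 / (2 * sigmas[k]^2))
  }
  new_profile(q, y, baseline_state = "subtracted")
}

# A minimal measured-style time course for the timecourse/kinetics tests.
toy_timecourse <- function(n = 12, pitch = 10, t0 = -22, stim = c(0, 50)) {
  t <- t0 + (seq_len(n) - 1) * pitch
  new_timecourse(
    tibble::tibble(frame = seq_len(n), time_ms = t,
                   force = pmax(0, plogis((t - 40) / 15)) * 100,
                   I_M3 = 1 - 0.3 * plogis((t - 30) / 10),
                   S_M3 = 14.442 + 0.1 * plogis((t - 60) / 15)),
    stimulus_times = stim
  )
}
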