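#' Simulation configuration for a fixed-end contraction protocol
#'
#' Builds the configuration consumed by [simulate_timecourse_truth()]. The
#' defaults emulate a fixed-end tetanus of rat soleus muscle at 27-28 C:
#' a 237 ms train of stimuli (last stimulus at 234 ms), 64 detector frames of
#' 10 ms pitch whose timestamps are the centres of the 8 ms integration
#' windows, force rising sigmoidally with a 72.3 ms half-time to ~106 kPa,
#' isometric (linear) relaxation at 1.7 s^-1 followed by exponential
#' relaxation at 23 s^-1, sarcomeres shortening from 2.43 to 2.15 um, the
#' 1,0 lattice spacing moving from 39.10 to 39.70 nm, the M3 and M6 myosin
#' meridionals moving from 14.442/7.230 nm to 14.558/7.292 nm, and the
#' intensity observables following the rest -> plateau levels and half-times
#' of the tetanus columns of the summary tables. The twitch protocol uses
#' 70 frames of 5 ms pitch and a single stimulus.
#'
#' Each structural series follows a clamped logistic (zero before the first
#' stimulus), or the sum of two opposite-sign clamped logistics for the
#' biphasic observables (I_M3, S_M3), multiplied during relaxation by a
#' linear-then-exponential envelope (tetanus) or by a falling logistic
#' (twitch).
#'
#' @param protocol `"tetanus"` or `"twitch"`.
#' @param n_frames,frame_pitch_ms,t_first_frame_ms Frame count, spacing and
#'   first-frame timestamp (ms, centre of integration window).
#' @param seed Master seed; per-frame rendering substreams are derived from
#'   it deterministically.
#' @param series Optional named list overriding rows of the series table
#'   (each element a named list of fields to replace).
#' @param amps Optional named list overriding rendered peak amplitudes
#'   (counts per pixel at the reflection centre).
#' @param background Optional overrides of the diffuse-background model
#'   (`c1`, `l1`, `c2`, `l2`, `aniso`).
#' @return A list of class `xfd_sim_config`.
#' @export
sim_config <- function(protocol = c("tetanus", "twitch"),
                       n_frames = NULL, frame_pitch_ms = NULL,
                       t_first_frame_ms = NULL, seed = 1L,
                       series = list(), amps = list(), background = list()) {
  protocol <- match.arg(protocol)
  if (protocol == "tetanus") {
    n_frames <- n_frames %||% 64L
    frame_pitch_ms <- frame_pitch_ms %||% 10
    t_first_frame_ms <- t_first_frame_ms %||% -22
    stimulus_times <- seq(0, 234, length.out = 20)
    exposure <- 8
  } else {
    n_frames <- n_frames %||% 70L
    frame_pitch_ms <- frame_pitch_ms %||% 5
    t_first_frame_ms <- t_first_frame_ms %||% -15.5
    stimulus_times <- 0
    exposure <- 4.5
  }
  if (frame_pitch_ms <= 0) abort("frame spacing must be positive")

  tab <- default_series_table(protocol)
  for (nm in names(series)) {
    i <- match(nm, tab$name)
    if (is.na(i)) abort(paste0("unknown series '", nm, "'"))
    for (f in names(series[[nm]])) tab[[f]][i] <- series[[nm]][[f]]
  }
  validate_series_table(tab)

  amps0 <- list(
    eq = 3000, i20_frac = 0.20,
    m3 = 700, m3l = 60, extras = 25,
    m6 = 500, m6l = 40,
    m7 = 120, m8 = 120, broad_frac = 0.06,
    ml1 = 150, al1 = 120, al6 = 80,
    samp_101 = 120, samp_111 = 150, samp_201 = 70,
    samp_102 = 60, samp_112 = 90, samp_202 = 45,
    samp_103 = 90, samp_113 = 45,
    sarc14 = 6000, sarc1 = 4000
  )
  bg0 <- list(c1 = 2000, l1 = 0.012, c2 = 120, l2 = 0.10, aniso = 1.3)

  structure(
    list(protocol = protocol, n_frames = as.integer(n_frames),
         frame_pitch_ms = frame_pitch_ms, t_first_frame_ms = t_first_frame_ms,
         stimulus_times = stimulus_times, exposure = exposure,
         seed = as.integer(seed), series = tab,
         amps = modifyList(amps0, amps),
         background = modifyList(bg0, background)),
    class = "xfd_sim_config"
  )
}

# One row per simulated observable. kind: "sigmoid" (single clamped logistic
# rest -> active) or "double" (fast branch of amplitude dev_fast plus slow
# branch of amplitude active - rest - dev_fast). k_slow/k_fast are the
# linear/exponential relaxation rate constants (s^-1); th_rel/tau_rel the
# twitch relaxation logistic. Levels and half-times follow the tetanus and
# twitch summary tables for rat soleus.
default_series_table <- function(protocol) {
  t <- tibble(
    name  = c("force", "SL", "d10", "I_10", "I_11", "I_M3", "S_M3",
              "I_M6", "S_M6", "I_ML1", "I_AL1", "I_AL6",
              "I_101", "I_1121", "I_102", "I_112", "I_103", "I_113",
              "bg_scale"),
    rest  = c(0.65, 2430, 39.10, 1, 0.58, 1, 14.442,
              1, 7.230, 1, 1, 1,
              1, 1, 1, 1, 1, 1,
              1),
    active = c(105.8, 2150, 39.70, 0.55, 0.748, 0.87, 14.558,
               0.77, 7.292, 0.55, 1.37, 1.59,
               0.60, 0.39, 0.0, 0.45, 0.10, 0.10,
               1.10),
    kind  = c("sigmoid", "sigmoid", "sigmoid", "sigmoid", "sigmoid",
              "double", "double",
              "sigmoid", "sigmoid", "sigmoid", "sigmoid", "sigmoid",
              "sigmoid", "sigmoid", "sigmoid", "sigmoid", "sigmoid", "sigmoid",
              "sigmoid"),
    t_half = c(72.3, 45, 61, 61, 61, 112.8, 78.3,
               50, 44.2, 72.7, 60, 60,
               47.9, 47.9, 40, 47.9, 40, 40,
               72.3),
    tau   = c(20, 14, 18, 18, 18, 30, 24,
              15, 13, 20, 18, 18,
              15, 15, 12, 15, 12, 12,
              20),
    dev_fast = c(0, 0, 0, 0, 0, -0.48, -0.050,
                 0, 0, 0, 0, 0,
                 0, 0, 0, 0, 0, 0,
                 0),
    t_half_fast = c(NA, NA, NA, NA, NA, 23.0, 17.1,
                    NA, NA, NA, NA, NA,
                    NA, NA, NA, NA, NA, NA,
                    NA),
    tau_fast = c(NA, NA, NA, NA, NA, 8, 6,
                 NA, NA, NA, NA, NA,
                 NA, NA, NA, NA, NA, NA,
                 NA),
    k_slow = c(1.7, 1.0, 1.0, 4.3, 4.3, 1.5, 4.3,
               1.5, 2.5, 1.7, 1.5, 1.5,
               0.9, 0.9, 0.9, 0.9, 0.9, 0.9,
               1.7),
    k_fast = c(23.0, 15, 10, 17.4, 17.4, 10, 53.4,
               12, 12.3, 11.1, 15, 15,
               8.8, 8.8, 8.8, 8.8, 8.8, 8.8,
               23.0)
  )
  if (protocol == "twitch") {
    tw <- list(
      force = c(18.76, 18.0), SL = c(2420, 15), d10 = c(37.66, 16),
      I_10 = c(0.85, 15.7), I_11 = c(0.527, 15.7),
      I_M3 = c(0.52, 9.9), S_M3 = c(14.446, 12),
      I_M6 = c(0.80, 15), S_M6 = c(7.242, 16.5),
      I_ML1 = c(0.92, 18), I_AL1 = c(1.41, 18), I_AL6 = c(1.28, 18),
      I_101 = c(0.65, 24.1), I_1121 = c(0.83, 24.1),
      I_102 = c(0.60, 20), I_112 = c(0.80, 24.1),
      I_103 = c(0.60, 20), I_113 = c(0.60, 20),
      bg_scale = c(1.005, 18.0)
    )
    for (nm in names(tw)) {
      i <- match(nm, t$name)
      t$active[i] <- tw[[nm]][1]
      t$t_half[i] <- tw[[nm]][2]
      t$tau[i] <- pmax(tw[[nm]][2] / 3.5, 2.5)
      t$kind[i] <- "sigmoid"
      t$dev_fast[i] <- 0
    }
    # twitch rest levels differ for the twitch batch of muscles
    t$rest[t$name == "SL"] <- 2460
    t$rest[t$name == "d10"] <- 37.86
    t$rest[t$name == "I_11"] <- 0.48 * t$rest[t$name == "I_10"]
    t$th_rel <- 35
    t$tau_rel <- 12
  } else {
    t$th_rel <- NA_real_
    t$tau_rel <- NA_real_
  }
  t
}

validate_series_table <- function(tab) {
  if (any(tab$active[tab$name == "force"] < 0) || tab$rest[tab$name == "force"] < 0)
    abort("force levels must be non-negative")
  for (nm in c("SL", "d10", "S_M3", "S_M6"))
    if (any(c(tab$rest[tab$name == nm], tab$active[tab$name == nm]) <= 0))
      abort(paste0(nm, " must stay positive"))
  if (any(tab$tau <= 0)) abort("sigmoid time constants must be positive")
  invisible(tab)
}

# Clamped logistic: 0 before the first stimulus, renormalised so the late
# plateau is exactly 1.
act_logistic <- function(t, t_half, tau) {
  s0 <- plogis(-t_half / tau)
  out <- (plogis((t - t_half) / tau) - s0) / (1 - s0)
  out[t < 0] <- 0
  pmax(out, 0)
}

# Relaxation envelope for the tetanus: 1 up to the first frame after the
# last stimulus, linear decay at k_slow (s^-1) to the start of exponential
# relaxation, then exponential decay at k_fast (s^-1).
relax_envelope <- function(t, k_slow, k_fast, t_lin = 244, t_exp = 344) {
  env <- rep(1, length(t))
  lin <- t > t_lin & t <= t_exp
  env[lin] <- 1 - k_slow * (t[lin] - t_lin) / 1000
  ex <- t > t_exp
  r_exp <- 1 - k_slow * (t_exp - t_lin) / 1000
  env[ex] <- r_exp * exp(-k_fast * (t[ex] - t_exp) / 1000)
  pmax(env, 0)
}

# Closed-form value of one simulated series at arbitrary times; this is the
# ground truth that rendered-and-analysed data are compared against.
series_value <- function(row, t, protocol, last_stimulus) {
  dev_total <- row$active - row$rest
  if (row$kind == "double") {
    dev <- row$dev_fast * act_logistic(t, row$t_half_fast, row$tau_fast) +
      (dev_total - row$dev_fast) * act_logistic(t, row$t_half, row$tau)
  } else {
    dev <- dev_total * act_logistic(t, row$t_half, row$tau)
  }
  if (protocol == "tetanus") {
    env <- relax_envelope(t, row$k_slow, row$k_fast)
  } else {
    # twitch relaxation: falling logistic whose half-time is referenced to
    # the end of the activation fitting window (t = 52.25 ms)
    centre <- 52.25 + row$th_rel
    env <- 1 - plogis((t - centre) / row$tau_rel)
    env <- env / (1 - plogis(-centre / row$tau_rel))
  }
  row$rest + dev * env
}

#' Evaluate a simulated ground-truth series on an arbitrary time grid
#'
#' Exposes the generator's closed form so tests and diagnostics can use a
#' densely evaluated oracle (e.g. to locate the biphasic minimum of I_M3 or
#' the half-maximum crossing of force).
#'
#' @param truth An `xfd_truth` from [simulate_timecourse_truth()].
#' @param name Series name (e.g. `"force"`, `"S_M3"`, `"I_1121"`).
#' @param t Times in ms since the first stimulus.
#' @return Numeric vector of series values.
#' @export
truth_series <- function(truth, name, t) {
  tab <- truth$config$series
  i <- match(name, tab$name)
  if (is.na(i)) abort(paste0("unknown series '", name, "'"))
  series_value(tab[i, ], t, truth$config$protocol, max(truth$stimulus_times))
}

#' Simulate ground-truth parameter time courses
#'
#' Evaluates every configured observable at the frame timestamps and tabulates
#' the per-frame reflection parameters used by [render_frame()].
#'
#' @param config An `xfd_sim_config` from [sim_config()].
#' @return An object of class `xfd_truth`: a list with `frames` (one row per
#'   frame: time, force, sarcomere length, lattice and meridional spacings,
#'   relative intensities, background scale), `config`, `stimulus_times` and
#'   `seed`.
#' @export
simulate_timecourse_truth <- function(config) {
  stopifnot(inherits(config, "xfd_sim_config"))
  times <- config$t_first_frame_ms + (seq_len(config$n_frames) - 1) * config$frame_pitch_ms
  if (!any(times < 0)) abort("protocol must include rest frames before the first stimulus")
  last_stim <- max(config$stimulus_times)
  vals <- lapply(seq_len(nrow(config$series)), function(i) {
    series_value(config$series[i, ], times, config$protocol, last_stim)
  })
  names(vals) <- config$series$name
  frames <- tibble(frame = seq_len(config$n_frames), time_ms = times)
  frames <- bind_cols(frames, as_tibble(vals))
  if (any(frames$force < 0) || any(frames$SL <= 0) || any(frames$d10 <= 0) ||
      any(frames$bg_scale <= 0))
    abort("simulated series violate type invariants")
  structure(
    list(frames = frames, config = config,
         stimulus_times = config$stimulus_times, seed = config$seed),
    class = "xfd_truth"
  )
}

#' @export
print.xfd_truth <- function(x, ...) {
  cat("<xfd_truth> ", x$config$protocol, ", ", nrow(x$frames), " frames, ",
      "seed ", x$seed, "\n", sep = "")
  print(x$frames, n = 5)
  invisible(x)
}

# Interference sub-peak layout: area fractions and spacing offsets (nm) of
# the low/mid/high-angle components, balanced so the amplitude-weighted mean
# spacing equals the series value exactly.
m3_subpeaks <- function() {
  tibble(sub = c("LA", "MA", "HA"),
         w = c(0.21, 0.55, 0.24),
         delta = c(0.25, 0, -0.21 * 0.25 / 0.24))
}
m6_subpeaks <- function() {
  tibble(sub = c("LA", "MA", "HA"),
         w = c(0.20, 0.60, 0.20),
         delta = c(0.06, 0, -0.06))
}

# Per-frame reflection parameter table for one camera. Columns: label,
# d_axial (nm, NA for equatorial reflections on the axis), q_radial (nm^-1),
# amplitude (expected peak counts/px), sigma_axial, sigma_radial (nm^-1).
reflection_table <- function(truth, frame_index, camera = c("saxs", "usaxs14", "usaxs1")) {
  camera <- match.arg(camera)
  fr <- truth$frames[frame_index, ]
  A <- truth$config$amps
  if (camera == "usaxs14") {
    orders <- seq(14L, 24L, by = 2L)
    return(tibble(
      label = paste0("SL", orders),
      d_axial = fr$SL / orders, q_radial = 0,
      amplitude = A$sarc14 * (14 / orders)^2,
      sigma_axial = 1e-5, sigma_radial = 3e-4
    ))
  }
  if (camera == "usaxs1") {
    orders <- 1:9
    return(tibble(
      label = paste0("SL", orders),
      d_axial = fr$SL / orders, q_radial = 0,
      amplitude = A$sarc1 * (1 / orders)^1.5,
      sigma_axial = 8e-6, sigma_radial = 3e-4
    ))
  }

  rows <- list()
  # Equatorials of the hexagonal lattice: 1,0 / 1,1 / 2,0.
  rows$eq <- tibble(
    label = c("1,0", "1,1", "2,0"),
    d_axial = NA_real_,
    q_radial = c(1, sqrt(3), 2) / fr$d10,
    amplitude = A$eq * c(fr$I_10, fr$I_11, A$i20_frac * fr$I_10),
    sigma_axial = 0.0020, sigma_radial = 0.0012
  )
  # Meridional clusters with interference sub-peaks; each sub-peak carries a
  # narrow and a broad cross-meridional component.
  merid <- function(base, S, Irel, sp, label, sig_ax) {
    d <- S + sp$delta
    amp <- base * sp$w * Irel
    bind_rows(
      tibble(label = paste0(label, "-", sp$sub), d_axial = d, q_radial = 0,
             amplitude = amp, sigma_axial = sig_ax, sigma_radial = 0.004),
      tibble(label = paste0(label, "-", sp$sub, "-broad"), d_axial = d, q_radial = 0,
             amplitude = amp * A$broad_frac, sigma_axial = sig_ax, sigma_radial = 0.020)
    )
  }
  rows$m3 <- merid(A$m3, fr$S_M3, fr$I_M3, m3_subpeaks(), "M3", 5e-4)
  rows$m6 <- merid(A$m6, fr$S_M6, fr$I_M6, m6_subpeaks(), "M6", 5e-4)
  rows$m3l <- tibble(label = "M3L", d_axial = 15.52, q_radial = 0,
                     amplitude = A$m3l, sigma_axial = 5e-4, sigma_radial = 0.004)
  rows$m6l <- tibble(label = "M6L", d_axial = 7.62, q_radial = 0,
                     amplitude = A$m6l, sigma_axial = 5e-4, sigma_radial = 0.004)
  rows$extras <- tibble(label = paste0("X", 1:4),
                        d_axial = 1 / c(0.0621, 0.0632, 0.0656, 0.0667),
                        q_radial = 0, amplitude = A$extras,
                        sigma_axial = 5e-4, sigma_radial = 0.004)
  # Higher myosin meridionals flanking AL6.
  rows$m78 <- bind_rows(
    tibble(label = c("M7", "M7-broad"), d_axial = 43.3 / 7, q_radial = 0,
           amplitude = A$m7 * c(1, 0.15), sigma_axial = 6e-4,
           sigma_radial = c(0.004, 0.020)),
    tibble(label = c("M8", "M8-broad"), d_axial = 43.3 / 8, q_radial = 0,
           amplitude = A$m8 * c(1, 0.15), sigma_axial = 6e-4,
           sigma_radial = c(0.004, 0.020))
  )
  # Layer lines: diffuse myosin ML1, actin AL1 at high radius, actin AL6.
  rows$ll <- tibble(
    label = c("ML1", "AL1", "AL6"),
    d_axial = c(43.3, 37.5, 5.905),
    q_radial = c(0.050, 0.100, 0.047),
    amplitude = c(A$ml1 * fr$I_ML1, A$al1 * fr$I_AL1, A$al6 * fr$I_AL6),
    sigma_axial = c(0.0012, 0.0013, 0.0008),
    sigma_radial = c(0.025, 0.022, 0.010)
  )
  # Sampled myosin layer-line spots on the simple lattice: columns at the
  # 1,0 / 1,1 / 2,0 lattice radii, rows at multiples of the 43.3 nm helix.
  qcol <- c(`10` = 1, `11` = sqrt(3), `20` = 2) / fr$d10
  rows$samp <- tibble(
    label = c("1,0,1", "1,1,1", "2,0,1", "1,0,2", "1,1,2", "2,0,2",
              "1,0,3", "1,1,3"),
    d_axial = 43.3 / c(1, 1, 1, 2, 2, 2, 3, 3),
    q_radial = unname(qcol[c("10", "11", "20", "10", "11", "20", "10", "11")]),
    amplitude = c(A$samp_101 * fr$I_101, A$samp_111 * fr$I_1121,
                  A$samp_201 * fr$I_1121, A$samp_102 * fr$I_102,
                  A$samp_112 * fr$I_112, A$samp_202 * fr$I_112,
                  A$samp_103 * fr$I_103, A$samp_113 * fr$I_113),
    sigma_axial = 0.0012, sigma_radial = 0.0018
  )
  out <- bind_rows(rows)
  out <- out[out$amplitude > 0, ]
  if (any(out$sigma_axial <= 0) || any(out$sigma_radial <= 0))
    abort("reflection widths must be positive")
  out
}
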