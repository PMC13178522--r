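# Structural-interpretation arithmetic: lattice geometry, muscle
# cross-section, per-filament and per-motor mechanics, and the
# square-of-diffractors state fractions.

#' Muscle cross-sectional area from wet weight
#'
#' CSA = W / (rho x L x fibre_fraction), with the wet weight in mg, density
#' in g cm^-3 and muscle length in mm; fibre length is taken as a fixed
#' fraction of muscle length.
#'
#' @param wet_weight_mg Muscle wet weight (mg).
#' @param density Muscle density (g cm^-3).
#' @param muscle_length_mm Optimal muscle length (mm).
#' @param fibre_fraction Fibre-to-muscle length ratio.
#' @return Cross-sectional area in mm^2.
#' @export
csa_from_mass <- function(wet_weight_mg, density = 1.06, muscle_length_mm,
                          fibre_fraction = 0.69) {
  if (any(c(wet_weight_mg, density, muscle_length_mm, fibre_fraction) <= 0))
    abort("all inputs must be positive")
  # g cm^-3 = 1e-3 g mm^-3; W in mg = 1e-3 g
  (wet_weight_mg * 1e-3) / (density * 1e-3 * muscle_length_mm * fibre_fraction)
}

#' Filament-lattice volume per sarcomere
#'
#' V = (2/sqrt(3)) x d10^2 x SL, the unit-cell volume of the hexagonal
#' filament lattice over one sarcomere.
#'
#' @param d10 Lattice 1,0 spacing (nm).
#' @param SL Sarcomere length (nm).
#' @return Volume in nm^3.
#' @export
lattice_volume <- function(d10, SL) {
  if (any(d10 <= 0) || any(SL <= 0)) abort("d10 and SL must be positive")
  (2 / sqrt(3)) * d10^2 * SL
}

#' Fractional lattice-volume change
#'
#' @param v_rest,v_active Lattice volumes (nm^3), e.g. from
#'   [lattice_volume()].
#' @return `v_active / v_rest - 1`.
#' @export
delta_volume <- function(v_rest, v_active) v_active / v_rest - 1

#' Cross-sectional area per thick filament
#'
#' The hexagonal unit-cell area, (2/sqrt(3)) x d10^2, i.e. the lattice
#' cross-section occupied by one thick filament.
#'
#' @param d10 Lattice 1,0 spacing (nm).
#' @return Area in nm^2.
#' @export
area_per_filament <- function(d10) {
  if (any(d10 <= 0)) abort("d10 must be positive")
  (2 / sqrt(3)) * d10^2
}

#' Per-filament and per-motor mechanics chain
#'
#' Converts a macroscopic isometric stress into per-motor mechanics:
#' myofibrillar stress (stress over the myofibrillar area fraction), force
#' per thick filament (stress x lattice area per filament; 1 kPa x nm^2 =
#' 1e-3 pN), the number of actin-attached motors per half filament, the
#' mean force per attached motor, its stiffness (force/strain), the work
#' done in one working stroke and the thermodynamic efficiency against the
#' free energy of ATP hydrolysis.
#'
#' @param stress_kPa Isometric force per muscle cross-sectional area (kPa).
#' @param myofibril_fraction Fraction of the cross-section occupied by
#'   myofibrils.
#' @param area_per_filament_nm2 Lattice cross-section per thick filament
#'   (nm^2).
#' @param motors_per_half_filament Myosin motors in each half thick
#'   filament.
#' @param attached_fraction Fraction of those motors attached to actin.
#' @param strain_nm Elastic strain of an attached motor (nm).
#' @param stroke_nm Working-stroke distance (nm).
#' @param atp_energy_pN_nm Free energy of ATP hydrolysis (pN nm).
#' @return One-row tibble with the full chain: `myofibrillar_stress_kPa`,
#'   `force_per_filament_pN`, `attached_motors`, `force_per_motor_pN`,
#'   `stiffness_pN_per_nm`, `work_per_motor_pN_nm`, `efficiency`.
#' @export
motor_mechanics <- function(stress_kPa, myofibril_fraction = 0.8,
                            area_per_filament_nm2 = area_per_filament(38.0),
                            motors_per_half_filament = 294,
                            attached_fraction, strain_nm = 4.5,
                            stroke_nm = 6, atp_energy_pN_nm = 100) {
  if (any(c(stress_kPa, myofibril_fraction, area_per_filament_nm2,
            motors_per_half_filament, attached_fraction, strain_nm,
            stroke_nm, atp_energy_pN_nm) <= 0))
    abort("all inputs must be positive")
  if (attached_fraction > 1) abort("attached_fraction must lie in (0, 1]")
  myofib_stress <- stress_kPa / myofibril_fraction
  force_per_fil <- myofib_stress * area_per_filament_nm2 * 1e-3  # pN
  attached <- attached_fraction * motors_per_half_filament
  if (attached < 1) warn("fewer than one attached motor per half filament")
  force_per_motor <- force_per_fil / attached
  tibble(
    myofibrillar_stress_kPa = myofib_stress,
    force_per_filament_pN = force_per_fil,
    attached_motors = attached,
    force_per_motor_pN = force_per_motor,
    stiffness_pN_per_nm = force_per_motor / strain_nm,
    work_per_motor_pN_nm = force_per_motor * stroke_nm,
    efficiency = force_per_motor * stroke_nm / atp_energy_pN_nm
  )
}

#' Motor-state fractions from relative diffracted intensities
#'
#' Diffracted intensity is proportional to the square of the number of
#' diffractors contributing to an ordered conformation, so the fraction of
#' motors remaining in that conformation is the square root of the relative
#' intensity. `released_fraction()` gives the fraction of motors released
#' from the folded OFF helix when its diffraction signal retains `I_rel` of
#' its resting intensity; `attached_ratio()` gives the relative number of
#' diffractors for actin-attachment signals.
#'
#' @param I_rel Intensity relative to rest (>= 0). Values above 1 are
#'   clipped with a warning for `released_fraction()` (more helical order
#'   than at rest).
#' @return `released_fraction()`: `1 - sqrt(I_rel)`; `attached_ratio()`:
#'   `sqrt(I_rel)`.
#' @export
released_fraction <- function(I_rel) {
  if (any(I_rel < 0)) abort("relative intensity must be non-negative")
  if (any(I_rel > 1)) {
    warn("relative intensity above 1 clipped (more helical order than rest)")
    I_rel <- pmin(I_rel, 1)
  }
  1 - sqrt(I_rel)
}

#' @rdname released_fraction
#' @export
attached_ratio <- function(I_rel) {
  if (any(I_rel < 0)) abort("relative intensity must be non-negative")
  sqrt(I_rel)
}
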