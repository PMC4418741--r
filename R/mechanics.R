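#' Fracture force by linear strain scaling
#'
#' In a linear-static model, strain is proportional to the applied force, so
#' the force needed to reach the yield strain of bone follows from the
#' strain computed at a reference load:
#' `F = F_applied * (eps_yield / eps_peak)`.
#'
#' @param F_applied reference applied force (N).
#' @param eps_peak peak von Mises strain in the fracture zone at that load
#'   (microstrain).
#' @param eps_yield assumed yield strain of bone (microstrain, default 6000).
#' @return force required for fracture (N).
#' @examples
#' fracture_force(56.1, 300)  # 1122
#' @export
fracture_force <- function(F_applied, eps_peak, eps_yield = 6000) {
  if (F_applied <= 0 || eps_yield <= 0) stop("forces and strains must be positive")
  if (eps_peak <= 0) stop("parameter error: eps_peak must be positive")
  F_applied * (eps_yield / eps_peak)
}

#' Equivalent static loading mass
#'
#' @param F force (N).
#' @param g gravitational acceleration (m/s^2, default 9.8).
#' @return mass in kg (F / g).
#' @export
equivalent_mass <- function(F, g = 9.8) {
  if (g <= 0) stop("g must be positive")
  F / g
}

#' Isometric body-mass estimate
#'
#' Scales a reference animal's mass by the cube of the length ratio
#' (isometry): `m = m_ref * (l / l_ref)^3`. Defaults use a 2 m, 50 kg
#' salamander-grade reference.
#'
#' @param l total length of the subject (m); vectorised.
#' @param l_ref,m_ref reference length (m) and mass (kg).
#' @return estimated mass in kg.
#' @examples
#' isometric_mass(c(1, 1.5))  # 6.25, 21.09
#' @export
isometric_mass <- function(l, l_ref = 2, m_ref = 50) {
  if (any(l <= 0) || l_ref <= 0 || m_ref <= 0) stop("lengths and masses must be positive")
  m_ref * (l / l_ref)^3
}

#' Force expressed in body weights
#'
#' @param F force (N).
#' @param body_mass subject mass (kg); vectorised.
#' @param g gravitational acceleration (m/s^2).
#' @return dimensionless ratio F / (body_mass * g).
#' @export
body_weight_ratio <- function(F, body_mass, g = 9.8) {
  if (F <= 0 || any(body_mass <= 0) || g <= 0) stop("inputs must be positive")
  F / (body_mass * g)
}

#' Minimum fall height producing a given impact force
#'
#' An animal of mass `m` decelerating from free fall to rest over a body
#' depth `s_d` experiences deceleration `a = F / m`; the free-fall velocity
#' it must have reached is `v_max = sqrt(2 a s_d)`, which requires a
#' free-fall drop of `v_max^2 / (2 g)`. The fall height is the drop plus the
#' deceleration distance. With `paper_rounding = TRUE` the free-fall drop is
#' rounded to 0.1 m before the sum, reproducing hand arithmetic conventions
#' used in worked examples; the exact value is always reported as well.
#'
#' @param F impact force (N).
#' @param m body mass (kg).
#' @param s_d deceleration distance, about the dorsoventral body depth (m).
#' @param g gravitational acceleration (m/s^2).
#' @param paper_rounding round the free-fall drop to 0.1 m before summing.
#' @return list: `a` (m/s^2), `v_max2` (m^2/s^2), `v_max` (m/s),
#'   `free_fall_m`, `height_m`, `height_exact_m`.
#' @examples
#' fall_height(1120, 25, 0.15)$height_exact_m  # 0.8357...
#' fall_height(1120, 25, 0.15, paper_rounding = TRUE)$height_m  # 0.85
#' @export
fall_height <- function(F, m, s_d, g = 9.8, paper_rounding = FALSE) {
  if (F <= 0 || m <= 0 || s_d <= 0 || g <= 0) stop("inputs must be positive")
  a <- F / m
  v_max2 <- 2 * a * s_d
  v_max <- sqrt(v_max2)
  ff_exact <- v_max2 / (2 * g)
  ff <- if (paper_rounding) round(ff_exact, 1) else ff_exact
  list(a = a, v_max2 = v_max2, v_max = v_max,
       free_fall_m = ff, height_m = ff + s_d,
       height_exact_m = ff_exact + s_d)
}

#' Impact force from fall height (inverse kinematics)
#'
#' Exact algebraic inverse of [fall_height()] without intermediate rounding:
#' `F = m g (s_h - s_d) / s_d`.
#'
#' @param s_h fall height (m), > `s_d`.
#' @param m body mass (kg).
#' @param s_d deceleration distance (m).
#' @param g gravitational acceleration (m/s^2).
#' @return force in N.
#' @export
impact_force_from_height <- function(s_h, m, s_d, g = 9.8) {
  if (s_h <= s_d) stop("parameter error: fall height must exceed deceleration distance")
  if (m <= 0 || s_d <= 0 || g <= 0) stop("inputs must be positive")
  m * g * (s_h - s_d) / s_d
}

#' Isometric rescaling of the deceleration distance
#'
#' The deceleration distance tracks the dorsoventral body depth, a linear
#' dimension, so under isometry it scales with the cube root of the mass
#' ratio.
#'
#' @param s_d reference deceleration distance (m).
#' @param m_new,m_ref new and reference masses (kg).
#' @return rescaled distance (m).
#' @export
scale_deceleration_distance <- function(s_d, m_new, m_ref) {
  if (s_d <= 0 || m_new <= 0 || m_ref <= 0) stop("inputs must be positive")
  s_d * (m_new / m_ref)^(1 / 3)
}

#' The full fracture-to-fall inference chain
#'
#' Propagates a finite-element reference solution (applied force and peak
#' fracture-zone strain) through force extrapolation, equivalent loading
#' mass, isometric body-mass bounds, body-weight ratios, and fall kinematics
#' for one or more candidate body masses.
#'
#' @param F_applied reference FE load (N).
#' @param eps_peak peak von Mises strain at that load (microstrain).
#' @param eps_yield yield strain (microstrain).
#' @param g gravitational acceleration (m/s^2).
#' @param body_lengths subject total lengths (m) for the isometric mass range.
#' @param body_weight_masses body-mass range (kg) over which to express the
#'   force in body weights.
#' @param assumed_masses body masses (kg) for the fall scenarios.
#' @param s_d deceleration distance (m) at the reference (largest) mass.
#' @param round_force_sig round the fracture force to this many significant
#'   figures before the downstream chain (3, as in hand-worked reporting);
#'   use NA for no rounding.
#' @return list of class `fall_scenario_chain`.
#' @export
fracture_scenario_chain <- function(F_applied = 56.1, eps_peak = 300,
                                    eps_yield = 6000, g = 9.8,
                                    body_lengths = c(1, 1.5),
                                    body_weight_masses = c(10, 25),
                                    assumed_masses = c(25, 15),
                                    s_d = 0.15, round_force_sig = 3) {
  F_exact <- fracture_force(F_applied, eps_peak, eps_yield)
  F <- if (is.na(round_force_sig)) F_exact else signif(F_exact, round_force_sig)
  m_load <- equivalent_mass(F, g)
  m_body <- isometric_mass(body_lengths)
  bw <- body_weight_ratio(F, body_weight_masses, g)
  m_ref <- max(assumed_masses)
  falls <- lapply(assumed_masses, function(mi) {
    sdi <- scale_deceleration_distance(s_d, mi, m_ref)
    c(list(mass_kg = mi, s_d_m = sdi),
      fall_height(F, mi, sdi, g, paper_rounding = TRUE))
  })
  structure(list(F_applied = F_applied, eps_peak = eps_peak,
                 eps_yield = eps_yield, g = g,
                 fracture_force_exact_N = F_exact, fracture_force_N = F,
                 equivalent_mass_kg = m_load,
                 body_lengths_m = body_lengths,
                 isometric_masses_kg = m_body,
                 assumed_masses_kg = assumed_masses,
                 body_weight_masses_kg = body_weight_masses,
                 body_weight_ratios = bw,
                 falls = falls),
            class = "fall_scenario_chain")
}

#' @export
print.fall_scenario_chain <- function(x, ...) {
  cat(sprintf("Fracture force: %.0f N (exact %.1f N) from %.1f N at %.0f/%.0f microstrain\n",
              x$fracture_force_N, x$fracture_force_exact_N, x$F_applied,
              x$eps_yield, x$eps_peak))
  cat(sprintf("Equivalent loading mass: %.1f kg\n", x$equivalent_mass_kg))
  cat(sprintf("Isometric body mass for %s m: %s kg\n",
              paste(x$body_lengths_m, collapse = "-"),
              paste(sprintf("%.1f", x$isometric_masses_kg), collapse = "-")))
  cat(sprintf("Force in body weights (%s kg): %s\n",
              paste(x$body_weight_masses_kg, collapse = ", "),
              paste(sprintf("%.1f", x$body_weight_ratios), collapse = ", ")))
  for (f in x$falls)
    cat(sprintf("Fall: m = %.0f kg, s_d = %.3f m -> v_max = %.2f m/s, height %.2f m (exact %.3f m)\n",
                f$mass_kg, f$s_d_m, f$v_max, f$height_m, f$height_exact_m))
  invisible(x)
}
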