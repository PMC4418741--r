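#' Density-to-modulus power law
#'
#' Young's modulus from apparent density via the power-law regression
#' E = 0.001 * rho^1.3266 with E in GPa and rho in kg/m3, optionally rounded
#' to the nearest 0.5 GPa to acknowledge the uncertainty of the mapping.
#' Input density is in g/cm3 (1 g/cm3 = 1000 kg/m3) and the returned
#' modulus is in MPa.
#'
#' @param rho density in g/cm3 (> 0); vectorised.
#' @param round_half_gpa round to the nearest 0.5 GPa before returning.
#' @param a,b regression constants (GPa scale).
#' @return Young's modulus in MPa.
#' @examples
#' density_to_modulus(1.4)          # 15000
#' density_to_modulus(1.4, FALSE)   # unrounded regression value
#' @export
density_to_modulus <- function(rho, round_half_gpa = TRUE,
                               a = 0.001, b = 1.3266) {
  if (any(rho <= 0)) stop("parameter error: density must be positive")
  e_gpa <- a * (1000 * rho)^b
  if (round_half_gpa) e_gpa <- round(e_gpa * 2) / 2
  e_gpa * 1000
}

#' Volume-weighted homogenised density
#'
#' @param class_densities densities (g/cm3), one per class.
#' @param class_volumes volumes (mm3), one per class.
#' @return sum(rho_i V_i) / sum(V_i), in g/cm3.
#' @examples
#' homogenize(c(1.6, 1.4, 1.2, 1.1), rep(1, 4))  # 1.325
#' @export
homogenize <- function(class_densities, class_volumes) {
  if (length(class_densities) != length(class_volumes))
    stop("class density and volume lists must have equal length")
  if (any(class_densities <= 0) || any(class_volumes < 0))
    stop("densities must be positive and volumes non-negative")
  tv <- sum(class_volumes)
  if (tv == 0) stop("zero total volume")
  sum(class_densities * class_volumes) / tv
}

#' Total mesh mass
#'
#' @param mesh a [tet_mesh()].
#' @param density per-element density in g/cm3.
#' @return mass in grams.
#' @export
total_mass <- function(mesh, density) {
  v <- tet_volumes(mesh)
  if (any(v <= 0)) stop("mesh-quality error: inverted element present")
  if (length(density) != length(v))
    stop("one density per element required")
  sum(density * v) / 1000           # g/cm3 * mm3 -> g
}

#' Reference cortical bone properties
#'
#' Fixed literature values used for the cortical shell (density 2.06 g/cm3,
#' E = 20 GPa, nu = 0.4); cortical bone is deliberately not put through the
#' cancellous density-modulus regression.
#' @return list with `rho`, `E_mpa`, `nu`.
#' @export
cortical_properties <- function() list(rho = 2.06, E_mpa = 20000, nu = 0.4)

#' Build a material card for density classes
#'
#' Maps each class density to elastic properties: cancellous classes get the
#' power-law modulus (rounded to 0.5 GPa) and nu = 0.3; the cortical class
#' (id 1) gets the fixed cortical values. Each row records both the rounded
#' and the unrounded regression modulus, and `flag` marks classes whose
#' conventional tabulated modulus (if supplied) disagrees with the
#' regression-plus-rounding value.
#'
#' @param class_densities densities in g/cm3, indexed by class id; id 1 is
#'   cortical, ids 2.. are cancellous.
#' @param nominal_E_mpa optional vector of tabulated moduli to check the
#'   regression against (NA to skip a class).
#' @return data.frame of class `material_card` with columns `class`, `rho`,
#'   `E_mpa`, `E_regression_mpa`, `nu`, `flag`.
#' @export
material_card <- function(class_densities, nominal_E_mpa = NULL) {
  k <- length(class_densities)
  cort <- cortical_properties()
  E_reg <- density_to_modulus(class_densities, round_half_gpa = FALSE)
  E_rnd <- density_to_modulus(class_densities, round_half_gpa = TRUE)
  E <- E_rnd; nu <- rep(0.3, k)
  E[1] <- cort$E_mpa; nu[1] <- cort$nu
  flag <- rep(FALSE, k)
  if (!is.null(nominal_E_mpa)) {
    chk <- seq_len(k)[-1]
    flag[chk] <- !is.na(nominal_E_mpa[chk]) & nominal_E_mpa[chk] != E_rnd[chk]
    E[chk] <- ifelse(flag[chk], nominal_E_mpa[chk], E[chk])
  }
  out <- data.frame(class = seq_len(k), rho = class_densities, E_mpa = E,
                    E_regression_mpa = E_reg, nu = nu, flag = flag)
  class(out) <- c("material_card", "data.frame")
  out
}
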