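#' Physical constants and reduced-unit conversions
#'
#' The simulation runs in reduced units: the length unit \eqn{\sigma} is the
#' van der Waals diameter of the sulfur atom (nominally 3.6 Angstrom), the
#' energy unit is \eqn{k_B T} at 298 K, charges are in elementary charges
#' and masses are 1 per site.  Physical units enter only through two
#' conversions: the Debye conversion for dipole moments (1 e Angstrom =
#' 4.80320 D) and the Bjerrum length that fixes the absolute electrostatic
#' coupling.
#'
#' @name units
#' @keywords internal
NULL

## 1 e*Angstrom in Debye
DEBYE_PER_E_ANGSTROM <- 4.80320

## default sigma in Angstrom (van der Waals diameter of S), used only for
## Debye / Bjerrum conversions; dynamics is in reduced units throughout
SIGMA_ANGSTROM <- 3.6

#' Bjerrum length
#'
#' Distance at which two elementary charges in a uniform medium of relative
#' permittivity `eps_r` interact with thermal energy \eqn{k_B T}:
#' \eqn{\lambda_B = e^2 / (4 \pi \varepsilon_0 \varepsilon_r k_B T)}.
#'
#' @param eps_r relative permittivity (dimensionless, > 0)
#' @param temperature_k absolute temperature in Kelvin (default 298)
#' @return Bjerrum length in Angstrom.
#' @examples
#' bjerrum_length(80)   # ~7 Angstrom in water
#' bjerrum_length(47)   # ~11.9 Angstrom in DMSO
#' @export
bjerrum_length <- function(eps_r, temperature_k = 298) {
  if (!is.numeric(eps_r) || any(eps_r <= 0))
    stop("eps_r must be positive", call. = FALSE)
  e  <- 1.602176634e-19     # C
  e0 <- 8.8541878128e-12    # F/m
  kB <- 1.380649e-23        # J/K
  lb_m <- e^2 / (4 * pi * e0 * eps_r * kB * temperature_k)
  lb_m * 1e10
}

#' Reduced Coulomb coupling constant
#'
#' Prefactor `C` such that the pair energy in reduced units is
#' `C * qi * qj / (eps_r * r)` with `r` in sigma and charges in e.  Equal to
#' the vacuum Bjerrum length expressed in sigma units, so it is exactly
#' inversely proportional to `eps_r` once divided through.
#'
#' @param sigma_angstrom physical length of one sigma, in Angstrom
#' @param temperature_k temperature in Kelvin used for the Bjerrum length
#' @return dimensionless coupling (sigma * kT / e^2).
#' @export
coulomb_coupling <- function(sigma_angstrom = SIGMA_ANGSTROM,
                             temperature_k = 298) {
  bjerrum_length(1, temperature_k) / sigma_angstrom
}
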