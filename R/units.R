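#' Physical constants (kcal/mol, Angstrom, e units)
#'
#' `kB` is the Boltzmann constant in kcal/mol/K; `kC` the Coulomb constant in
#' kcal*A/(mol*e^2). Internal time is a reduced CG unit; the mapping to
#' physical time is user-supplied metadata, never applied internally.
#' @keywords internal
#' @name constants
NULL

.kB <- 0.0019872041
.kC <- 332.0637

#' Debye screening length
#'
#' Closed-form Debye length for a monovalent salt solution,
#' \eqn{\lambda_D = \sqrt{\epsilon_r \epsilon_0 k_B T / (2 N_A e^2 I)}},
#' with the ionic strength `I` equal to the molar salt concentration.
#'
#' @param temperature temperature in K.
#' @param salt monovalent salt concentration in mol/L.
#' @param dielectric relative dielectric constant (default 78).
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(300, 0.21) # ~6.6 A at physiological-like salt
#' @export
debye_length <- function(temperature = 300, salt = 0.21, dielectric = 78) {
  stopifnot(temperature > 0, salt > 0, dielectric > 0)
  eps0 <- 8.8541878128e-12   # F/m
  kB_J <- 1.380649e-23       # J/K
  NA_  <- 6.02214076e23      # 1/mol
  e    <- 1.602176634e-19    # C
  I_m3 <- salt * 1000 * NA_  # ions per m^3 per species
  lam_m <- sqrt(dielectric * eps0 * kB_J * temperature / (2 * e^2 * I_m3))
  lam_m * 1e10
}
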