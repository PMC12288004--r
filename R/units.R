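#' Physical constants and the internal unit system
#'
#' The package works throughout in kcal/mol (energy), Angstrom (length),
#' femtosecond (time), atomic mass unit (mass) and elementary charge.
#' All constants are derived at load time from CODATA 2018 exact values,
#' never transcribed from secondary sources.
#'
#' * `ke_coulomb()` — Coulomb prefactor, kcal.A/(mol.e^2): 332.0637.
#' * `kB_kcal()` — Boltzmann constant as a molar gas constant, kcal/(mol.K).
#' * `kcal_per_mdunit()` — kcal/mol per internal dynamic unit amu.A^2/fs^2.
#'
#' One internal dynamic unit is 1e-3 kg/mol x 1e10 m^2/s^2 = 1e7 J/mol,
#' so 1 kcal/mol = 4184/1e7 = 4.184e-4 amu.A^2/fs^2 exactly.
#'
#' @return A single numeric value.
#' @name units
NULL

# CODATA 2018 exact defining constants (SI)
.const <- new.env(parent = baseenv())
.const$e_C       <- 1.602176634e-19    # elementary charge, C
.const$N_A       <- 6.02214076e23      # Avogadro, 1/mol
.const$kB_SI     <- 1.380649e-23       # Boltzmann, J/K
.const$eps0      <- 8.8541878128e-12   # vacuum permittivity, F/m (CODATA 2018)
.const$J_per_kcal <- 4184              # thermochemical calorie

#' @rdname units
#' @export
ke_coulomb <- function() {
  with(.const, (e_C^2 * N_A / (4 * pi * eps0)) * 1e10 / J_per_kcal)
}

#' @rdname units
#' @export
kB_kcal <- function() {
  with(.const, kB_SI * N_A / J_per_kcal)
}

#' @rdname units
#' @export
kcal_per_mdunit <- function() {
  # 1 amu.A^2/fs^2 = 1e7 J/mol
  1e7 / .const$J_per_kcal
}

# conversion used in hot loops, computed once at load
.KE    <- NULL  # Coulomb constant
.KB    <- NULL  # kcal/(mol K)
.MDU   <- NULL  # kcal/mol per amu A^2/fs^2
.KCAL2MDU <- NULL

.onLoad <- function(libname, pkgname) {
  ns <- topenv()
  assign(".KE",  ke_coulomb(), envir = ns)
  assign(".KB",  kB_kcal(), envir = ns)
  assign(".MDU", kcal_per_mdunit(), envir = ns)
  assign(".KCAL2MDU", 1 / kcal_per_mdunit(), envir = ns)
}
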