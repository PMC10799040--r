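#' Unit system constants
#'
#' The package works in a fixed internal unit system: length in Angstrom (A),
#' time in picoseconds (ps), energy in kcal/mol, charge in elementary charges
#' (e), mass in g/mol, temperature in Kelvin. `des_units()` returns the named
#' constants used throughout:
#'
#' * `k_B` — Boltzmann constant, 0.0019872041 kcal mol^-1 K^-1.
#' * `k_C` — Coulomb constant, 332.0636 kcal A mol^-1 e^-2 (the common
#'   biomolecular force-field convention). The relative stability factor is a
#'   ratio of energies, so this choice cancels there.
#' * `kcal_per_g_to_A2ps2` — conversion of kcal mol^-1 / (g mol^-1) to
#'   A^2 ps^-2 (= 418.4, from 1 kcal = 4184 J); used to express thermal
#'   velocity variance k_B T / m in internal velocity units.
#' * `bohr_per_angstrom` — 1/0.529177210903, used when writing Gaussian cube
#'   files.
#' * `mPas_per_internal_viscosity` — conversion of the internal Green-Kubo
#'   viscosity unit (kcal mol^-1 A^-3 ps) to mPa s, derived from the
#'   Avogadro constant and 1 kcal = 4184 J.
#'
#' @return Named list of numeric constants.
#' @export
#' @examples
#' des_units()$k_B
des_units <- function() {
  avogadro <- 6.02214076e23
  joule_per_kcal <- 4184
  # kcal mol^-1 A^-3 ps  ->  Pa s: (J / m^3) * s, then * 1e3 for mPa s
  visc <- joule_per_kcal / avogadro / 1e-30 * 1e-12 * 1e3
  list(
    k_B = 0.0019872041,
    k_C = 332.0636,
    kcal_per_g_to_A2ps2 = joule_per_kcal / 10,
    bohr_per_angstrom = 1 / 0.529177210903,
    mPas_per_internal_viscosity = visc,
    length = "angstrom",
    time = "ps",
    energy = "kcal/mol",
    charge = "e"
  )
}

# standard atomic masses (g/mol) for the elements the fixtures and DES
# systems use; lookup is case-sensitive on the element symbol
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904,
  X = 1.0
)

#' Look up atomic masses by element symbol
#'
#' @param elements Character vector of element symbols (e.g. `"Cl"`).
#' @return Numeric vector of masses in g/mol.
#' @export
element_mass <- function(elements) {
  m <- .element_masses[elements]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
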