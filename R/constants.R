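# Physical constants (CODATA 2018) and unit conversions.
#
# Internal unit system used throughout the package:
#   energy      kJ mol^-1
#   length      Angstrom
#   mass        amu (= g mol^-1)
#   charge      elementary charge e
#   pressure    GPa
#   temperature K
#   frequency   cm^-1 (wavenumber)

.const <- local({
  avogadro <- 6.02214076e23
  e_charge <- 1.602176634e-19    # C
  eps0     <- 8.8541878128e-12   # F m^-1
  h_planck <- 6.62607015e-34     # J s
  c_cm     <- 2.99792458e10      # cm s^-1
  kB_J     <- 1.380649e-23       # J K^-1

  list(
    avogadro = avogadro,
    # Coulomb constant, kJ mol^-1 Angstrom e^-2
    k_coulomb = e_charge^2 * avogadro / (4 * pi * eps0 * 1e-10) / 1000,
    # Boltzmann constant, kJ mol^-1 K^-1
    kB = kB_J * avogadro / 1000,
    # energy of one wavenumber quantum h*c*nu, kJ mol^-1 per cm^-1
    cm1_to_kjmol = h_planck * c_cm * avogadro / 1000,
    # sqrt(eigenvalue in kJ mol^-1 amu^-1 A^-2) -> wavenumber in cm^-1:
    # 1 kJ mol^-1 amu^-1 A^-2 = 1e26 s^-2
    freq_to_cm1 = sqrt(1e26) / (2 * pi * c_cm),
    # kJ mol^-1 A^-3 -> GPa
    kjmolA3_to_GPa = 1e33 / (avogadro * 1e9),
    # GPa * A^3 -> kJ mol^-1 (for P*V terms)
    GPaA3_to_kjmol = avogadro * 1e9 * 1e-30 / 1000
  )
})

#' Physical constants used by polyphonon
#'
#' Returns the package's centralized table of physical constants and unit
#' conversion factors (CODATA 2018). All energies are molar (kJ mol^-1),
#' lengths in Angstrom, masses in amu, frequencies in wavenumbers.
#'
#' @return Named list with elements `avogadro`, `k_coulomb`
#'   (kJ mol^-1 A e^-2), `kB` (kJ mol^-1 K^-1), `cm1_to_kjmol`,
#'   `freq_to_cm1`, `kjmolA3_to_GPa` and `GPaA3_to_kjmol`.
#' @examples
#' physical_constants()$k_coulomb  # ~1389.35
#' @export
physical_constants <- function() .const

# Standard atomic weights (amu), common elements for organic molecular
# crystals plus a few inorganic ions used by the test lattices.
.atomic_masses <- c(
  H = 1.008, He = 4.0026, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403, Ne = 20.1797, Na = 22.98977, Mg = 24.305, Al = 26.9815,
  Si = 28.085, P = 30.97376, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.0983, Ca = 40.078, Br = 79.904, I = 126.90447, Cs = 132.90545
)

# Covalent radii in Angstrom (Cordero et al. 2008 consensus values),
# used by the bond-graph molecule identification.
.covalent_radii <- c(
  H = 0.31, He = 0.28, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
  F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76,
  Br = 1.20, I = 1.39, Cs = 2.44
)

#' Standard atomic mass of an element
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of masses in amu.
#' @export
atomic_mass <- function(element) {
  m <- .atomic_masses[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Covalent radius of an element
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    stop("no covalent radius tabulated for: ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# classed error helpers -------------------------------------------------

stop_polyphonon <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "polyphonon_error")))
}

stop_format <- function(msg) stop_polyphonon(msg, "polyphonon_format_error")
stop_value <- function(msg) stop_polyphonon(msg, "polyphonon_value_error")
stop_geometry <- function(msg) stop_polyphonon(msg, "polyphonon_geometry_error")
stop_instability <- function(msg) stop_polyphonon(msg, "polyphonon_instability_error")
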