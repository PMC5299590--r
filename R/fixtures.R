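# Deterministic toy crystals with analytic or brute-force oracles. These
# stand in for real molecular crystal structures so that every part of the
# engine (energies, phonons, quasi-harmonic expansion, elastic moduli,
# polymorph comparison) can be tested end to end without external data.
#
# Force constants are chosen so that phonon frequencies fall in the
# 10-200 cm^-1 lattice-mode range typical of organic molecular crystals,
# keeping the computed thermodynamics in a realistic regime.

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("fixture '%s': %d atoms, %d molecules, V = %.2f A^3\n",
              x$name, nrow(x$crystal$atoms), n_molecules(x$crystal),
              cell_volume(x$crystal)))
  invisible(x)
}

#' Monatomic bead-spring chain crystal with analytic dispersion
#'
#' A simple-cubic crystal of beads connected to their six nearest
#' neighbours by harmonic springs with zero rest length. Along each axis
#' the dispersion is exactly the textbook monatomic-chain result
#' `omega(k) = 2 sqrt(kappa/m) |sin(k a / 2)|` for all three
#' polarizations (the zero rest length makes each bond isotropic, which
#' also provides the transverse confinement while preserving translational
#' invariance, hence the acoustic sum rule). The crystal is elastically
#' isotropic.
#'
#' @param kappa Spring constant, kJ mol^-1 A^-2.
#' @param m Bead mass, amu.
#' @param a Lattice spacing, Angstrom.
#' @param n Suggested number of sampled cells along the chain direction
#'   (the k-grid `c(n, 1, 1)`); must be >= 2.
#' @return Object of class `fixture` with elements `crystal`, `ff`,
#'   `oracle` (`dispersion(kfrac)` in cm^-1, `debye_velocity` in
#'   cm^-1 Angstrom) and `grid`.
#' @export
chain_1d <- function(kappa = 10, m = 40, a = 5, n = 12) {
  if (kappa <= 0 || m <= 0 || a <= 0) {
    stop_value("kappa, m and a must be positive")
  }
  if (n < 2) stop_value("need at least 2 cells along the chain")
  ff <- forcefield(
    types = data.frame(label = "X", element = "Ar", mass = m, charge = 0,
                       stringsAsFactors = FALSE),
    springs = data.frame(t1 = "X", t2 = "X", kappa = kappa, r0 = 0,
                         rcut = 1.3 * a, stringsAsFactors = FALSE),
    com_cutoff = 2 * a, taper = 0)
  cr <- crystal(diag(3) * a,
                data.frame(element = "Ar", mass = m, x = 0, y = 0, z = 0,
                           charge = 0, ff_type = "X",
                           stringsAsFactors = FALSE))
  w0 <- 2 * sqrt(kappa / m) * .const$freq_to_cm1
  structure(list(
    name = "chain_1d", crystal = cr, ff = ff, grid = c(n, 1L, 1L),
    oracle = list(
      dispersion = function(kfrac) w0 * abs(sin(pi * kfrac)),
      max_freq = w0,
      debye_velocity = a * sqrt(kappa / m) * .const$freq_to_cm1,
      provenance = "analytic nearest-neighbour harmonic chain")),
    class = "fixture")
}

#' Exp-6 face-centred cubic crystal
#'
#' A four-atom conventional fcc cell bound by a single exp-6 interaction,
#' optimized to its lattice-energy minimum at construction. The stiffness
#' is chosen to give a molecular-crystal-like bulk modulus (~10 GPa) and
#' lattice modes up to ~125 cm^-1. The oracle evaluates explicit
#' `E_latt(V)` and `A(V, T) = E_latt(V) + F_vib(V, T)` scans by direct
#' computation on isotropically scaled structures, independent of the
#' thermal-pressure path.
#'
#' @param a_param,b_param,c_param Exp-6 parameters A (kJ mol^-1),
#'   B (A^-1), C (kJ mol^-1 A^6).
#' @param mass Atom mass, amu.
#' @param a0 Starting lattice parameter, Angstrom.
#' @return Object of class `fixture`: optimized `crystal`, `ff`, and
#'   `oracle` with `energy_volume(svals)`, `free_energy_volume(svals, T,
#'   grid)` and the relaxed `v0` per molecule.
#' @export
exp6_fcc <- function(a_param = 4e5, b_param = 3.0, c_param = 25200,
                     mass = 39.948, a0 = 5.2) {
  if (a_param <= 0 || c_param <= 0 || b_param <= 0) {
    stop_value("exp-6 fcc fixture needs positive A, B, C (bound minimum)")
  }
  ff <- forcefield(
    types = data.frame(label = "Ar", element = "Ar", mass = mass, charge = 0,
                       stringsAsFactors = FALSE),
    pairs = data.frame(t1 = "Ar", t2 = "Ar", A = a_param, B = b_param,
                       C = c_param, stringsAsFactors = FALSE),
    com_cutoff = 20)
  at <- data.frame(element = "Ar", mass = mass,
                   x = c(0, .5, .5, 0), y = c(0, .5, 0, .5),
                   z = c(0, 0, .5, .5), charge = 0, ff_type = "Ar",
                   stringsAsFactors = FALSE)
  cr <- tryCatch(
    optimize_crystal(crystal(diag(3) * a0, at), ff)$crystal,
    polyphonon_instability_error = function(e) stop_value(
      "parameters do not give a bound fcc crystal (relaxation unbinds it)"))
  if (lattice_energy(cr, ff)$e_inter >= 0) {
    stop_value("parameters do not give a bound fcc crystal")
  }
  oracle_ev <- function(svals) {
    do.call(rbind, lapply(svals, function(s) {
      c2 <- .isotropic_scale(cr, s^(1 / 3))
      data.frame(s = s, v = cell_volume(c2) / 4,
                 e_latt = lattice_energy(c2, ff)$e_inter)
    }))
  }
  oracle_av <- function(svals, T, grid = c(4, 4, 4), zpe_pressure = TRUE) {
    do.call(rbind, lapply(svals, function(s) {
      c2 <- .isotropic_scale(cr, s^(1 / 3))
      sp <- sample_spectrum(c2, ff, grid = grid)
      ts <- vib_free_energy(sp, T)
      fv <- if (zpe_pressure) ts$f_vib else ts$f_vib - ts$zpe
      data.frame(s = s, v = cell_volume(c2) / 4, a = sp$e_latt + fv)
    }))
  }
  structure(list(
    name = "exp6_fcc", crystal = cr, ff = ff, grid = c(4L, 4L, 4L),
    oracle = list(
      v0 = cell_volume(cr) / 4,
      energy_volume = oracle_ev,
      free_energy_volume = oracle_av,
      provenance = "direct evaluation on isotropically scaled structures")),
    class = "fixture")
}

# starting motifs for the two diatomic packings: relaxed representative
# geometries (lattice row-major; per molecule the fractional position of
# the first atom and the Cartesian unit vector of the bond). "alpha" is a
# parallel-aligned packing, "beta" a tilted antiparallel (herringbone-like)
# one; both relax to distinct mechanically stable minima of the default
# force field.
.diatomic_motifs <- list(
  alpha = list(
    lattice = matrix(c(5.174005, 0, 0,
                       1.040379, 3.872220, 0,
                       0, 0, 3.270115), 3, 3, byrow = TRUE),
    c_frac = matrix(c(0.033250, 0.107550, 0.119960,
                      0.533250, 0.607550, 0.619960), 2, 3, byrow = TRUE),
    u = matrix(c(-0.683666, -0.729795, 0,
                 -0.683666, -0.729795, 0), 2, 3, byrow = TRUE)),
  beta = list(
    lattice = matrix(c(5.861005, 0, 0,
                       0, 3.369272, 0,
                       0, 0.049707, 3.368906), 3, 3, byrow = TRUE),
    c_frac = matrix(c(0.995460, 0.054572, 0.990373,
                      0.495460, 0.436122, 0.608823), 2, 3, byrow = TRUE),
    u = matrix(c(0.856248, -0.362562, 0.367951,
                 0.856248, 0.362562, -0.367951), 2, 3, byrow = TRUE))
)

#' Rigid diatomic molecular crystal (synthetic polymorph pair)
#'
#' A rigid heteronuclear diatomic (C-O like, point charges +/- q) packed
#' in one of two antiparallel motifs, `"alpha"` and `"beta"`, which relax
#' to distinct mechanically stable minima of the same force field: a
#' synthetic polymorph pair exercising librations, electrostatics and the
#' full comparison pipeline. Generation optimizes the motif and verifies
#' phonon stability on a 3x3x3 grid; an unstable result is an error.
#'
#' @param bond Bond length, Angstrom.
#' @param q Charge magnitude on the two atoms (+q on C, -q on O), e.
#' @param packing `"alpha"` or `"beta"`.
#' @return Object of class `fixture` with the relaxed `crystal`, `ff` and
#'   an oracle carrying the relaxed enthalpy per molecule.
#' @export
rigid_diatomic_crystal <- function(bond = 1.1, q = 0.15,
                                   packing = c("alpha", "beta")) {
  packing <- match.arg(packing)
  if (bond <= 0) stop_value("bond length must be positive")
  ff <- forcefield(
    types = data.frame(label = c("C1", "O1"), element = c("C", "O"),
                       mass = c(12.011, 15.999), charge = c(q, -q),
                       stringsAsFactors = FALSE),
    pairs = data.frame(t1 = c("C1", "C1", "O1"), t2 = c("C1", "O1", "O1"),
                       A = c(1.5e5, 2e5, 2.5e5), B = c(3.6, 3.7, 3.8),
                       C = c(2000, 2200, 2400), stringsAsFactors = FALSE),
    com_cutoff = 10)
  mo <- .diatomic_motifs[[packing]]
  L <- mo$lattice
  at <- NULL; units <- list()
  for (i in seq_len(nrow(mo$c_frac))) {
    cpos <- mo$c_frac[i, ]
    cart_c <- cpos %*% L
    fr_o <- (cart_c + mo$u[i, ] * bond) %*% solve(L)
    at <- rbind(at, data.frame(
      element = c("C", "O"),
      x = c(cpos[1], fr_o[1]), y = c(cpos[2], fr_o[2]),
      z = c(cpos[3], fr_o[3]),
      charge = c(q, -q), ff_type = c("C1", "O1"),
      stringsAsFactors = FALSE))
    units[[i]] <- (2 * i - 2) + 1:2
  }
  start <- crystal(L, at, units)
  op <- tryCatch(
    optimize_crystal(start, ff, check_change = FALSE),
    error = function(e) stop_polyphonon(
      sprintf("packing '%s' failed to relax (%s); try a longer bond or smaller q",
              packing, conditionMessage(e)),
      "polyphonon_generation_error"))
  cr <- op$crystal
  ok <- tryCatch({
    sample_spectrum(cr, ff, grid = c(3, 3, 3))
    TRUE
  }, polyphonon_instability_error = function(e) FALSE)
  if (!ok) {
    stop_polyphonon(
      sprintf("packing '%s' relaxed to an unstable structure at bond = %g, q = %g; try a longer bond or smaller q",
              packing, bond, q),
      "polyphonon_generation_error")
  }
  structure(list(
    name = paste0("diatomic_", packing), crystal = cr, ff = ff,
    grid = c(3L, 3L, 3L),
    oracle = list(enthalpy = op$enthalpy,
                  provenance = "relaxed and stability-verified at generation")),
    class = "fixture")
}

#' Synthetic ensemble of polymorph-pair energy differences
#'
#' Draws an ensemble of pairwise free-energy differences with the
#' structure of a large polymorph survey: lattice-energy differences,
#' harmonic vibrational contributions, and a thermal-expansion (QHA minus
#' HA) contribution that is normally distributed about zero with standard
#' deviation `sigma_dd` (0.42 kJ mol^-1 by default, the survey value for
#' that contribution).
#'
#' @param n Number of pairs.
#' @param sigma_dd Standard deviation of the pairwise thermal-expansion
#'   contribution, kJ mol^-1.
#' @param seed Mandatory RNG seed; generation is fully deterministic.
#' @param sigma_elatt,sigma_vib Standard deviations of the lattice-energy
#'   difference and of the harmonic vibrational contribution at the
#'   melting point, kJ mol^-1.
#' @return data.frame with columns `pair`, `d_elatt`, `d_a0`, `d_a_tm`,
#'   `d_qha_ha` and `t_m`, suitable for [survey()].
#' @export
synthetic_pair_ensemble <- function(n, sigma_dd = 0.42, seed,
                                    sigma_elatt = 2.0, sigma_vib = 0.8) {
  if (n < 1) stop_value("need at least one pair")
  if (missing(seed)) stop_value("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d_elatt <- stats::rnorm(n, 0, sigma_elatt)
  d_zpe <- stats::rnorm(n, 0, 0.3)
  d_vib <- stats::rnorm(n, 0, sigma_vib)
  d_qha_ha <- stats::rnorm(n, 0, sigma_dd)
  t_m <- stats::rnorm(n, 410, 40)
  data.frame(pair = seq_len(n),
             d_elatt = d_elatt,
             d_a0 = d_elatt + d_zpe,
             d_a_tm = d_elatt + d_zpe + d_vib + d_qha_ha,
             d_qha_ha = d_qha_ha,
             t_m = t_m)
}
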