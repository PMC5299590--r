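# Quasi-harmonic approximation by the thermal-pressure method: the volume
# derivative of the vibrational free energy defines a thermal pressure
# P_th(T) = -dF_vib/dV; a static rigid-body optimization at -P_th yields
# the thermally expanded structure, on which phonons and free energies are
# recomputed: A_QHA(T) = E_latt(T) + F_vib(T).

# isotropically scale a crystal to volume V*(scale^3): lattice scales,
# molecular centres of mass move affinely, rigid geometry is unchanged.
.isotropic_scale <- function(crystal, scale) {
  geom <- .mol_geometry(crystal)
  cr <- crystal
  cr$lattice <- crystal$lattice * scale
  Linv <- solve(cr$lattice)
  for (u in seq_len(n_molecules(crystal))) {
    idx <- crystal$rigid_units[[u]]
    m <- crystal$atoms$mass[idx]
    com <- colSums(geom$xyz[idx, , drop = FALSE] * m) / sum(m)
    rel <- sweep(geom$xyz[idx, , drop = FALSE], 2, com)
    newx <- sweep(rel, 2, com * scale, "+")
    cr$atoms[idx, c("x", "y", "z")] <- (newx %*% Linv) %% 1
  }
  cr
}

# vibrational free energy per cell at temperature T (optionally the
# thermal part only, ZPE removed)
.fvib_cell <- function(crystal, ff, T, grid, thermal_only) {
  sp <- sample_spectrum(crystal, ff, grid = grid)
  ts <- vib_free_energy(sp, T)
  f <- if (thermal_only) ts$f_vib - ts$zpe else ts$f_vib
  f * n_molecules(crystal)
}

#' Thermal pressure -dF_vib/dV
#'
#' Central finite difference of the vibrational free energy over crystals
#' isotropically scaled to V(1 +/- dV_frac), with rigid-unit geometry fixed
#' and centres of mass moved affinely. Softening of the spectrum upon
#' expansion gives a positive thermal pressure.
#'
#' By default only the thermal part of F_vib enters (the zero-point volume
#' derivative is excluded, so P_th(0) = 0): empirical force fields fitted
#' to low-temperature crystal structures already contain the zero-point
#' expansion implicitly. Set `zpe_pressure = TRUE` to include it.
#'
#' @param crystal A stable `crystal` at its 0 K minimum.
#' @param ff A `forcefield`.
#' @param T Temperature, K.
#' @param dV_frac Relative volume step (0 < dV_frac <= 0.02).
#' @param grid Phonon k-grid used for F_vib.
#' @param zpe_pressure Include the zero-point volume derivative.
#' @return Thermal pressure in GPa.
#' @export
thermal_pressure <- function(crystal, ff, T, dV_frac = 0.005,
                             grid = c(4, 4, 4), zpe_pressure = FALSE) {
  if (dV_frac <= 0 || dV_frac > 0.02) {
    stop_value("dV_frac must be in (0, 0.02]")
  }
  V0 <- cell_volume(crystal)
  sp <- (1 + dV_frac)^(1 / 3)
  sm <- (1 - dV_frac)^(1 / 3)
  thermal_only <- !zpe_pressure
  fp <- .fvib_cell(.isotropic_scale(crystal, sp), ff, T, grid, thermal_only)
  fm <- .fvib_cell(.isotropic_scale(crystal, sm), ff, T, grid, thermal_only)
  dFdV <- (fp - fm) / (2 * V0 * dV_frac)          # kJ mol^-1 A^-3
  -dFdV * .const$kjmolA3_to_GPa
}

#' Quasi-harmonic state at one temperature
#'
#' Computes the thermal pressure at the reference (0 K) structure,
#' optimizes the crystal at the negative thermal pressure to obtain the
#' thermally expanded structure, and recomputes the spectrum and
#' vibrational free energy there: `A_QHA(T) = E_latt(T) + F_vib(T)`.
#' At the default settings P_th(0) = 0 and the 0 K state satisfies
#' `A_QHA(0) = A_HA(0) = E_latt + ZPE` identically.
#'
#' The thermal pressure is iterated to self-consistency: after each
#' expansion it is re-evaluated at the expanded structure until the volume
#' is converged, so the result satisfies the same stationarity condition
#' `d(E_latt + F_vib)/dV = 0` as an explicit free-energy minimization over
#' volume. `max_scf = 1` recovers the single-pass scheme (P_th from the
#' 0 K reference only).
#'
#' @inheritParams thermal_pressure
#' @param opt_tol Gradient tolerance passed to [optimize_crystal()].
#' @param max_scf Maximum thermal-pressure self-consistency iterations.
#' @param v_tol Relative volume convergence threshold for the iteration.
#' @return Object of class `qha_result`: `T`, `p_thermal` (GPa),
#'   `expanded` (crystal), `e_latt_T`, `f_vib_T`, `a_qha`, `entropy`,
#'   `zpe`, `volume`, `alpha_v` (vs the reference structure).
#' @export
qha_state <- function(crystal, ff, T, dV_frac = 0.005, grid = c(4, 4, 4),
                      zpe_pressure = FALSE, opt_tol = 1e-4, max_scf = 12,
                      v_tol = 2e-4) {
  V0 <- cell_volume(crystal)
  expanded <- crystal
  pth <- 0
  if (!(T == 0 && !zpe_pressure)) {
    for (it in seq_len(max_scf)) {
      pth_new <- thermal_pressure(expanded, ff, T, dV_frac, grid,
                                  zpe_pressure)
      Vprev <- cell_volume(expanded)
      expanded <- optimize_crystal(crystal, ff, pressure = -pth_new,
                                   tol = opt_tol)$crystal
      pth <- pth_new
      if (abs(cell_volume(expanded) - Vprev) < v_tol * Vprev) break
    }
  }
  sp <- sample_spectrum(expanded, ff, grid = grid)
  ts <- vib_free_energy(sp, T)
  VT <- cell_volume(expanded)
  structure(list(
    T = T, p_thermal = pth, expanded = expanded,
    e_latt_T = sp$e_latt, f_vib_T = ts$f_vib,
    a_qha = sp$e_latt + ts$f_vib, entropy = ts$entropy, zpe = ts$zpe,
    volume = VT / n_molecules(crystal),
    alpha_v = if (T > 0) expansion_coefficient(V0, VT, T) else 0),
    class = "qha_result")
}

#' @export
print.qha_result <- function(x, ...) {
  cat(sprintf(
    "QHA %.0f K: P_th = %.4f GPa, V = %.3f A^3/molecule, A_QHA = %.4f kJ/mol, alpha_V = %.1f x 1e-6/K\n",
    x$T, x$p_thermal, x$volume, x$a_qha, x$alpha_v * 1e6))
  invisible(x)
}

#' Volumetric thermal expansion coefficient by finite difference
#'
#' `alpha_V = (V_T - V_0) / (V_0 * dT)`, the linear finite-difference
#' expansion coefficient between a reference and an expanded structure.
#'
#' @param v0 Reference volume (A^3).
#' @param vT Expanded volume at `dT` above the reference (A^3).
#' @param dT Temperature interval, K.
#' @return Expansion coefficient in K^-1 (multiply by 1e6 for the
#'   conventional 1e-6/K reporting unit).
#' @export
expansion_coefficient <- function(v0, vT, dT) {
  if (v0 <= 0 || dT <= 0) stop_value("v0 and dT must be positive")
  (vT - v0) / (v0 * dT)
}

#' Free-energy curve by cubic Hermite interpolation
#'
#' Builds a piecewise cubic through free-energy nodes using the analytic
#' entropies as slopes (`dA/dT = -S`), so the interpolant honours both the
#' free energies and their first derivatives.
#'
#' @param states List of `thermo_state` or `qha_result` objects (or a
#'   data.frame with columns `T`, `A`, `S`), at strictly increasing
#'   temperatures, at least two.
#' @return Object of class `free_energy_curve` with `nodes` and an
#'   evaluator; use [predict.free_energy_curve()].
#' @export
free_energy_curve <- function(states) {
  if (is.data.frame(states)) {
    nodes <- states[, c("T", "A", "S")]
  } else {
    nodes <- do.call(rbind, lapply(states, function(s) {
      if (inherits(s, "qha_result")) {
        data.frame(T = s$T, A = s$a_qha, S = s$entropy)
      } else if (inherits(s, "thermo_state")) {
        data.frame(T = s$T, A = s$a_ha, S = s$entropy)
      } else stop_value("states must be thermo_state or qha_result objects")
    }))
  }
  if (nrow(nodes) < 2) stop_value("need at least two free-energy nodes")
  if (any(diff(nodes$T) <= 0)) stop_value("temperatures must be increasing")
  structure(list(nodes = nodes), class = "free_energy_curve")
}

#' Evaluate a free-energy curve
#'
#' @param object A `free_energy_curve`.
#' @param T Temperatures inside the node range.
#' @param deriv 0 for A(T), 1 for dA/dT (= -S).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.free_energy_curve <- function(object, T, deriv = 0, ...) {
  nd <- object$nodes
  if (any(T < min(nd$T) - 1e-9) || any(T > max(nd$T) + 1e-9)) {
    stop_value("temperature outside the interpolation range")
  }
  vapply(T, function(tt) {
    i <- findInterval(tt, nd$T, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(nd) - 1L)
    h <- nd$T[i + 1] - nd$T[i]
    s <- (tt - nd$T[i]) / h
    m0 <- -nd$S[i] * h; m1 <- -nd$S[i + 1] * h
    a0 <- nd$A[i]; a1 <- nd$A[i + 1]
    if (deriv == 0) {
      (2 * s^3 - 3 * s^2 + 1) * a0 + (s^3 - 2 * s^2 + s) * m0 +
        (-2 * s^3 + 3 * s^2) * a1 + (s^3 - s^2) * m1
    } else {
      ((6 * s^2 - 6 * s) * a0 + (3 * s^2 - 4 * s + 1) * m0 +
         (-6 * s^2 + 6 * s) * a1 + (3 * s^2 - 2 * s) * m1) / h
    }
  }, numeric(1))
}

#' @export
print.free_energy_curve <- function(x, ...) {
  cat(sprintf("free-energy curve: %d nodes on [%.0f, %.0f] K\n",
              nrow(x$nodes), min(x$nodes$T), max(x$nodes$T)))
  invisible(x)
}

#' Transition temperature(s) between two free-energy curves
#'
#' Finds the roots of `A_B(T) - A_A(T)` on the overlap of the two curves'
#' temperature ranges by sign-change bracketing and bisection.
#'
#' @param curveA,curveB `free_energy_curve` objects with overlapping
#'   ranges.
#' @param n Scan resolution.
#' @return Sorted numeric vector of crossing temperatures (K); `numeric(0)`
#'   when the curves do not cross; attribute `degenerate` is set when the
#'   curves coincide within 1e-10 everywhere.
#' @export
transition_temperature <- function(curveA, curveB, n = 2000) {
  lo <- max(min(curveA$nodes$T), min(curveB$nodes$T))
  hi <- min(max(curveA$nodes$T), max(curveB$nodes$T))
  if (hi <= lo) stop_value("curves have no overlapping temperature range")
  tt <- seq(lo, hi, length.out = n)
  d <- predict(curveB, tt) - predict(curveA, tt)
  if (max(abs(d)) < 1e-10) {
    out <- numeric(0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  roots <- c()
  sgn <- sign(d)
  for (i in seq_len(n - 1)) {
    if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
      r <- stats::uniroot(function(x) predict(curveB, x) - predict(curveA, x),
                          c(tt[i], tt[i + 1]), tol = 1e-8)$root
      roots <- c(roots, r)
    } else if (sgn[i + 1] == 0 && i + 1 == n) {
      roots <- c(roots, tt[i + 1])
    }
  }
  sort(unique(roots))
}
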