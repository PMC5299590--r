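# Rigid-body + unit-cell lattice-energy minimization at an applied external
# pressure (including the negative thermal pressure of the quasi-harmonic
# scheme).
#
# Parametrization: the cell is the 6 free entries of a lower-triangular
# lattice matrix (which pins the global orientation); each rigid unit moves
# by a Cartesian centre-of-mass displacement and an axis-angle rotation
# increment about its centre of mass (composed on restarts, avoiding Euler
# singularities). The first unit's translation is fixed to remove uniform
# drift. Gradients are central finite differences; minimization is
# quasi-Newton (L-BFGS-B) with re-centred restarts.

.rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  n <- w / th
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# right Jacobian of SO(3) for the composition Exp(w + dw) ~ Exp(w) Exp(J dw)
.so3_right_jacobian <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-8) return(diag(3))
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) - (1 - cos(th)) / th^2 * K + (th - sin(th)) / th^3 * (K %*% K)
}

# canonical lower-triangular lattice (rotates the crystal, energies invariant)
.canonical_lattice <- function(lattice) {
  G <- lattice %*% t(lattice)
  t(chol(G))
}

# pack a crystal into the optimizer's reference frame
.opt_reference <- function(crystal) {
  L0 <- .canonical_lattice(crystal$lattice)
  cr <- crystal
  cr$lattice <- L0
  geom <- .mol_geometry(cr)
  M <- n_molecules(cr)
  units <- vector("list", M)
  for (u in seq_len(M)) {
    idx <- cr$rigid_units[[u]]
    m <- cr$atoms$mass[idx]
    com <- colSums(geom$xyz[idx, , drop = FALSE] * m) / sum(m)
    rel <- sweep(geom$xyz[idx, , drop = FALSE], 2, com)
    nrot <- 0L; axes <- NULL
    if (length(idx) > 1) {
      inert <- matrix(0, 3, 3)
      for (jj in seq_along(idx)) {
        r <- rel[jj, ]
        inert <- inert + m[jj] * (sum(r^2) * diag(3) - tcrossprod(r))
      }
      ev <- eigen(inert, symmetric = TRUE)
      keep <- ev$values > 1e-8 * max(ev$values)
      axes <- ev$vectors[, keep, drop = FALSE]
      nrot <- ncol(axes)
      if (nrot == 3L) axes <- diag(3)   # nonlinear: plain Cartesian basis
    }
    units[[u]] <- list(idx = idx, com = com, rel = rel,
                       frac_com = drop(com %*% solve(L0)),
                       nrot = nrot, axes = axes)
  }
  list(crystal = cr, L0 = L0, units = units)
}

.opt_nparam <- function(ref, fix_cell) {
  M <- length(ref$units)
  nc <- if (fix_cell) 0L else 6L
  nt <- 3L * max(M - 1L, 0L)
  if (M == 1L) nt <- 0L
  nr <- sum(vapply(ref$units, function(u) u$nrot, 1L))
  c(cell = nc, trans = nt, rot = nr)
}

.opt_build <- function(ref, p, fix_cell) {
  M <- length(ref$units)
  if (fix_cell) {
    L <- ref$L0
    off <- 0L
  } else {
    L <- matrix(0, 3, 3)
    L[1, 1] <- p[1]; L[2, 1] <- p[2]; L[2, 2] <- p[3]
    L[3, 1] <- p[4]; L[3, 2] <- p[5]; L[3, 3] <- p[6]
    off <- 6L
  }
  cr <- ref$crystal
  cr$lattice <- L
  Linv <- solve(L)
  for (u in seq_len(M)) {
    un <- ref$units[[u]]
    delta <- c(0, 0, 0)
    if (u > 1L) {
      delta <- p[off + 1:3]; off <- off + 3L
    }
    w <- c(0, 0, 0)
    if (un$nrot > 0L) {
      th <- p[off + seq_len(un$nrot)]; off <- off + un$nrot
      w <- drop(un$axes %*% th)
    }
    com <- drop(un$frac_com %*% L) + delta
    R <- .rodrigues(w)
    newx <- sweep(un$rel %*% t(R), 2, com, "+")
    cr$atoms[un$idx, c("x", "y", "z")] <- (newx %*% Linv) %% 1
  }
  cr
}

.opt_p0 <- function(ref, fix_cell) {
  p <- if (fix_cell) numeric(0) else {
    L <- ref$L0
    c(L[1, 1], L[2, 1], L[2, 2], L[3, 1], L[3, 2], L[3, 3])
  }
  for (u in seq_along(ref$units)) {
    if (u > 1L) p <- c(p, 0, 0, 0)
    p <- c(p, numeric(ref$units[[u]]$nrot))
  }
  p
}

#' Minimize the lattice enthalpy of a rigid-body crystal
#'
#' Relaxes the 6 cell degrees of freedom plus rigid-body translations and
#' rotations of every molecule at an applied external pressure, minimizing
#' `E_inter + P*V` per molecule. Supplying the negative thermal pressure
#' yields the thermally expanded quasi-harmonic structure.
#'
#' @param crystal Starting `crystal` (non-overlapping).
#' @param ff A `forcefield`.
#' @param pressure External pressure, GPa (negative values expand).
#' @param tol Convergence threshold on the infinity norm of the gradient
#'   (kJ mol^-1 per Angstrom / radian).
#' @param max_iter Iteration budget per L-BFGS-B restart.
#' @param fix_cell Optimize molecular positions only, cell frozen (used for
#'   the internal relaxation of strained cells).
#' @param max_restarts Number of re-centred restarts.
#' @param check_change If `TRUE` (default) raise an instability error when
#'   the relaxed structure changed drastically (volume change > 50% or a
#'   centre-of-mass displacement > 3 A), mirroring the exclusion of
#'   structures destabilized by negative pressure.
#' @return List of class `opt_result`: `crystal` (relaxed), `enthalpy`
#'   (kJ mol^-1 per molecule), `gradient_norm`, `n_iterations`,
#'   `converged`.
#' @export
optimize_crystal <- function(crystal, ff, pressure = 0, tol = 1e-4,
                             max_iter = 400, fix_cell = FALSE,
                             max_restarts = 6, check_change = TRUE) {
  M <- n_molecules(crystal)
  V0 <- cell_volume(crystal)
  ref0 <- .opt_reference(crystal)
  com0 <- t(vapply(ref0$units, function(u) u$com, numeric(3)))

  obj_factory <- function(ref) {
    function(p) {
      cr <- .opt_build(ref, p, fix_cell)
      # keep the search in the local basin: at negative pressure the
      # enthalpy is unbounded as V -> Inf, so a runaway line search must
      # be rejected rather than followed
      V <- det(cr$lattice)
      if (V < 0.05 * V0 || V > 2.5 * V0) return(1e10)
      eb <- tryCatch(lattice_energy(cr, ff, pressure),
                     polyphonon_geometry_error = function(e) NULL)
      if (is.null(eb)) return(1e10)
      eb$e_inter + eb$pv_term
    }
  }
  num_grad <- function(fn, p, h = 1e-4) {
    vapply(seq_along(p), function(i) {
      pp <- p; pp[i] <- pp[i] + h
      pm <- p; pm[i] <- pm[i] - h
      (fn(pp) - fn(pm)) / (2 * h)
    }, numeric(1))
  }
  # analytic gradient for the rigid-body dof (forces and torques from the
  # analytic atomic gradient, mapped through the SO(3) right Jacobian for
  # finite rotation-vector parameters); finite differences only for the 6
  # cell entries
  grad_factory <- function(ref, fn) {
    function(p, h = 1e-4) {
      g <- numeric(length(p))
      off <- 0L
      if (!fix_cell) {
        for (i in 1:6) {
          pp <- p; pp[i] <- pp[i] + h
          pm <- p; pm[i] <- pm[i] - h
          g[i] <- (fn(pp) - fn(pm)) / (2 * h)
        }
        off <- 6L
      }
      cr <- .opt_build(ref, p, fix_cell)
      ga <- tryCatch(atomic_gradient(cr, ff) / M,
                     error = function(e) NULL)
      if (is.null(ga)) return(num_grad(fn, p, h))
      for (u in seq_along(ref$units)) {
        un <- ref$units[[u]]
        if (u > 1L) {
          g[off + 1:3] <- colSums(ga[un$idx, , drop = FALSE])
          off <- off + 3L
        }
        if (un$nrot > 0L) {
          th <- p[off + seq_len(un$nrot)]
          w <- drop(un$axes %*% th)
          R <- .rodrigues(w)
          rel_cur <- un$rel %*% t(R)
          tau <- c(0, 0, 0)
          for (ii in seq_along(un$idx)) {
            tau <- tau + .cross3(rel_cur[ii, ], ga[un$idx[ii], ])
          }
          g[off + seq_len(un$nrot)] <-
            drop(t(un$axes) %*% (t(.so3_right_jacobian(w)) %*%
                                   (t(R) %*% tau)))
          off <- off + un$nrot
        }
      }
      g
    }
  }

  ref <- ref0
  total_iter <- 0L
  e_start <- NULL
  gnorm <- Inf
  for (rs in seq_len(max_restarts)) {
    fn <- obj_factory(ref)
    p <- .opt_p0(ref, fix_cell)
    if (length(p) == 0L) {   # single rigid atom, fixed cell: nothing to do
      cr <- ref$crystal
      e <- fn(p)
      return(structure(list(crystal = cr, enthalpy = e, gradient_norm = 0,
                            n_iterations = 0L, converged = TRUE),
                       class = "opt_result"))
    }
    if (is.null(e_start)) e_start <- fn(p)
    gradfn <- grad_factory(ref, fn)
    gnorm <- max(abs(gradfn(p)))
    if (gnorm < tol) {
      cr <- .opt_build(ref, p, fix_cell)
      return(structure(list(crystal = cr, enthalpy = fn(p),
                            gradient_norm = gnorm,
                            n_iterations = total_iter, converged = TRUE),
                       class = "opt_result"))
    }
    # box bounds keep every restart inside a trust region around the
    # current reference (cell entries +-15% + 0.4 A, translations +-2 A,
    # rotations +-0.8 rad); larger relaxations proceed across re-centred
    # restarts, while pathological line-search excursions are cut off
    lo <- p; hi <- p
    off <- 0L
    if (!fix_cell) {
      band <- 0.15 * abs(p[1:6]) + 0.4
      lo[1:6] <- p[1:6] - band; hi[1:6] <- p[1:6] + band
      off <- 6L
    }
    for (u in seq_along(ref$units)) {
      if (u > 1L) {
        lo[off + 1:3] <- -2; hi[off + 1:3] <- 2
        off <- off + 3L
      }
      nr <- ref$units[[u]]$nrot
      if (nr > 0L) {
        lo[off + seq_len(nr)] <- -0.8; hi[off + seq_len(nr)] <- 0.8
        off <- off + nr
      }
    }
    res <- stats::optim(p, fn, gr = grad_factory(ref, fn),
                        method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = max_iter, factr = 10,
                                       pgtol = tol / 20))
    total_iter <- total_iter + res$counts[1]
    cr <- .opt_build(ref, res$par, fix_cell)
    gnorm <- max(abs(gradfn(res$par)))
    ref <- .opt_reference(cr)   # re-centre the parametrization
    if (gnorm < tol) break
  }
  cr <- ref$crystal
  eb <- lattice_energy(cr, ff, pressure)
  enth <- eb$e_inter + eb$pv_term
  converged <- gnorm < tol
  if (check_change) {
    V1 <- cell_volume(cr)
    if (abs(V1 - V0) > 0.5 * V0) {
      stop_instability(sprintf(
        "structure drastically changed: volume %.1f -> %.1f A^3", V0, V1))
    }
    com1 <- t(vapply(.opt_reference(cr)$units, function(u) u$com, numeric(3)))
    # compare in fractional terms to ignore the lattice re-orientation
    d <- (com1 %*% solve(cr$lattice) - com0 %*% solve(ref0$L0))
    d <- d - round(d)
    dmax <- sqrt(max(rowSums((d %*% cr$lattice)^2)))
    if (dmax > 3) {
      stop_instability(sprintf(
        "structure drastically changed: rigid unit moved %.2f A", dmax))
    }
  }
  structure(list(crystal = cr, enthalpy = enth, gradient_norm = gnorm,
                 n_iterations = as.integer(total_iter),
                 converged = converged),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf(
    "optimization: H = %.6f kJ/mol per molecule, |grad| = %.2e, %d iterations, %s\n",
    x$enthalpy, x$gradient_norm, x$n_iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Mechanical and dynamical stability report
#'
#' Reports the minimum Gamma-point phonon eigenvalue beyond the three
#' acoustic zeros and (optionally) the definiteness of the elastic tensor.
#' A crystal is labelled stable when both are positive.
#'
#' @param crystal A `crystal` at a stationary point.
#' @param ff A `forcefield`.
#' @param elastic Also compute the elastic tensor (slower).
#' @return List of class `stability_report`: `min_phonon_freq` (signed
#'   cm^-1, beyond acoustic), `phonon_stable`, `elastic_definite`,
#'   `min_elastic_eig` (GPa) and `stable`.
#' @export
check_stability <- function(crystal, ff, elastic = TRUE) {
  Dm <- suppressWarnings(dynamical_matrix(crystal, ff, c(0, 0, 0)))
  lam <- sort(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values)
  nacoustic <- min(3L, length(lam))
  lam_rest <- sort(lam[order(abs(lam))][-(seq_len(nacoustic))])
  minfreq <- if (length(lam_rest)) .signed_freq(min(lam_rest)) else NA_real_
  phonon_ok <- is.na(minfreq) || minfreq > -0.5
  el_def <- NA; min_eig <- NA_real_
  if (elastic) {
    ct <- elastic_tensor(crystal, ff)
    ev <- eigen(ct$c, symmetric = TRUE, only.values = TRUE)$values
    min_eig <- min(ev)
    el_def <- min_eig > 0
  }
  structure(list(min_phonon_freq = minfreq, phonon_stable = phonon_ok,
                 elastic_definite = el_def, min_elastic_eig = min_eig,
                 stable = phonon_ok && !isFALSE(el_def)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "stability: min optic/librational frequency %.3f cm^-1; elastic min eig %s GPa; %s\n",
    x$min_phonon_freq,
    if (is.na(x$min_elastic_eig)) "n/a" else sprintf("%.3f", x$min_elastic_eig),
    if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}
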