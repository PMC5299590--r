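# Rigid-body lattice dynamics: analytic force constants, dynamical matrices
# at arbitrary k, uniform k-grid sampling with a Debye treatment of the
# acoustic branches and a Gaussian-KDE density of states for the optic
# branches, and harmonic vibrational thermodynamics.
#
# Conventions: the dynamical matrix is assembled in the "cell" gauge
# (phase e^{i k.R_l} on the lattice vector of the interacting image), which
# is the gauge in which a rigid-body mode gives one amplitude per molecule
# per cell. Rigid units contribute 3 translational degrees of freedom plus
# one librational degree per principal axis with non-zero moment of inertia
# (3 for a non-linear molecule, 2 for a linear one, 0 for a single atom).

.cross3 <- pracma_cross

# 3x3 Hessian block of a radial pair kernel, flattened column-major to 9.
# H = (d2 - d1/r) rhat rhat^T + (d1/r) I
.hess_blocks <- function(rvec, d1, d2) {
  r <- sqrt(rowSums(rvec^2))
  rh <- rvec / r
  a <- d2 - d1 / r
  b <- d1 / r
  H <- matrix(0, length(r), 9)
  cidx <- 1
  for (bcol in 1:3) for (arow in 1:3) {
    H[, cidx] <- a * rh[, arow] * rh[, bcol] + if (arow == bcol) b else 0
    cidx <- cidx + 1
  }
  H
}

# Assemble all real-space force-constant terms (ordered, half-weighted).
.fc_terms <- function(crystal, ff, geom) {
  q <- crystal$atoms$charge
  ilist <- list(); jlist <- list(); Rlist <- list(); Hlist <- list()
  push <- function(tm, d1, d2) {
    if (length(tm$i) == 0) return()
    ilist[[length(ilist) + 1L]] <<- tm$i
    jlist[[length(jlist) + 1L]] <<- tm$j
    Rlist[[length(Rlist) + 1L]] <<- tm$Rl
    # each ordered term describes one directed image bond; force-constant
    # blocks are full (energies use the 1/2 double-counting weight, the
    # dynamical matrix must not)
    Hlist[[length(Hlist) + 1L]] <<- .hess_blocks(tm$rvec, d1, d2)
  }
  sr <- .sr_terms(crystal, ff, geom)
  if (length(sr$i)) {
    r <- sqrt(rowSums(sr$rvec^2))
    ti <- crystal$atoms$ff_type[sr$i]; tj <- crystal$atoms$ff_type[sr$j]
    p <- ff_pair_params(ff, ti, tj)
    kd <- .kernel_d("exp6", list(A = p[, "A"], B = p[, "B"], C = p[, "C"]), r)
    d1 <- kd$d1; d2 <- kd$d2
    if (!is.null(ff$springs)) {
      s <- ff_spring_params(ff, ti, tj)
      act <- s[, "kappa"] > 0 & r < s[, "rcut"]
      if (any(act)) {
        d1[act] <- d1[act] + s[act, "kappa"] * (r[act] - s[act, "r0"])
        d2[act] <- d2[act] + s[act, "kappa"]
      }
    }
    # pair blocks are scaled by the cutoff taper weight; the (tiny)
    # taper-derivative cross terms are neglected in the force constants --
    # they involve only pairs at the far cutoff where the pair energy is
    # ~1e-3 kJ/mol, and they cannot violate the acoustic sum rule
    S <- .taper_S(sr$trip_rcom, ff$com_cutoff, ff$taper %||% 1)[sr$trip]
    push(sr, S * d1, S * d2)
  }
  ew <- NULL
  if (any(abs(q) > 1e-14)) {
    ew <- .ewald_setup(crystal, ff$ewald_accuracy)
    ct <- .coul_real_terms(crystal, ew, geom)
    if (length(ct$i)) {
      r <- sqrt(rowSums(ct$rvec^2))
      kd <- .kernel_d("coul", list(qq = q[ct$i] * q[ct$j], sign = 1), r,
                      alpha = ew$alpha)
      push(ct, kd$d1, kd$d2)
    }
    it <- .coul_intra_terms(crystal, geom)
    if (length(it$i)) {
      r <- sqrt(rowSums(it$rvec^2))
      kd <- .kernel_d("coul", list(qq = q[it$i] * q[it$j], sign = -1), r)
      push(it, kd$d1, kd$d2)
    }
  }
  list(i = unlist(ilist), j = unlist(jlist),
       Rl = do.call(rbind, Rlist), H = do.call(rbind, Hlist), ew = ew)
}

# Reciprocal-space Ewald contribution to the atomic dynamical matrix at
# kcart (cell gauge, 3na x 3na complex). Returns zero matrix if no charges.
.recip_dyn <- function(ctx, kcart) {
  na <- ctx$na
  D <- matrix(0 + 0i, 3 * na, 3 * na)
  if (is.null(ctx$ew)) return(D)
  Kall <- sweep(ctx$Gall, 2, kcart, "+")
  k2 <- rowSums(Kall^2)
  sel <- k2 > 1e-14
  Kall <- Kall[sel, , drop = FALSE]; k2 <- k2[sel]
  fK <- exp(-k2 / (4 * ctx$ew$alpha^2)) / k2
  pref <- .const$k_coulomb * 4 * pi / ctx$ew$V
  phi <- ctx$xyz %*% t(Kall)            # na x nK
  C <- cos(phi); S <- sin(phi)
  q <- ctx$q
  for (acomp in 1:3) for (bcomp in acomp:3) {
    w <- fK * Kall[, acomp] * Kall[, bcomp]
    Cw <- sweep(C, 2, w, "*"); Sw <- sweep(S, 2, w, "*")
    ReQ <- Cw %*% t(C) + Sw %*% t(S)
    ImQ <- Sw %*% t(C) - Cw %*% t(S)
    blk <- pref * outer(q, q) * (ReQ + 1i * ImQ)
    rows <- seq(acomp, 3 * na, by = 3)
    cols <- seq(bcomp, 3 * na, by = 3)
    D[rows, cols] <- D[rows, cols] + blk
    if (acomp != bcomp) {
      D[seq(bcomp, 3 * na, by = 3), seq(acomp, 3 * na, by = 3)] <-
        D[seq(bcomp, 3 * na, by = 3), seq(acomp, 3 * na, by = 3)] + blk
    }
  }
  # the K = k+G sum already carries the cell-gauge phase: Sum_l of the
  # erf-complement Hessian with e^{ik.R_l} Poisson-transforms to exactly
  # this expression (verified against supercell folding)
  D
}

# Precompute everything k-independent for dynamical matrices.
.dyn_context <- function(crystal, ff, warn_tol = 1e-2, quiet = FALSE) {
  geom <- .mol_geometry(crystal)
  na <- nrow(crystal$atoms)
  fc <- .fc_terms(crystal, ff, geom)
  q <- crystal$atoms$charge
  ctx <- list(crystal = crystal, ff = ff, na = na, xyz = geom$xyz,
              geom = geom, q = q, fc = fc, ew = fc$ew,
              B = 2 * pi * t(solve(crystal$lattice)),
              V = cell_volume(crystal))
  if (!is.null(fc$ew)) {
    ctx$Gall <- rbind(c(0, 0, 0), fc$ew$G)
    # exact reciprocal-part self term via the acoustic sum rule at Gamma
    Qg <- .recip_dyn(ctx, c(0, 0, 0))
    self <- matrix(0 + 0i, 3 * na, 3 * na)
    for (i in seq_len(na)) {
      ri <- (3 * i - 2):(3 * i)
      acc <- matrix(0 + 0i, 3, 3)
      for (j in seq_len(na)) acc <- acc + Qg[ri, (3 * j - 2):(3 * j)]
      self[ri, ri] <- -acc
    }
    ctx$recip_self <- self
  }
  # grouped real-space accumulation tables
  if (length(fc$i)) {
    ctx$key_off <- (fc$i - 1L) * na + fc$j
    ctx$diagH <- rowsum(fc$H, group = fc$i)        # k-independent self part
    ctx$diag_atoms <- as.integer(rownames(ctx$diagH))
  }
  # rigid units: projection, masses, gradient correction
  g <- atomic_gradient(crystal, ff)
  units <- crystal$rigid_units
  M <- length(units)
  dofs <- list(); tmass <- c(); Pmat <- NULL
  corr_blocks <- list()
  labels <- character()
  maxg <- 0
  for (u in seq_len(M)) {
    idx <- units[[u]]
    info <- rigid_unit_info(crystal, u)
    rho <- sweep(geom$xyz[idx, , drop = FALSE], 2, info$com)
    ev <- eigen(info$inertia_tensor, symmetric = TRUE)
    rot_ax <- ev$vectors[, ev$values > 1e-8 * max(ev$values, 1e-8),
                         drop = FALSE]
    moments <- ev$values[ev$values > 1e-8 * max(ev$values, 1e-8)]
    nd <- 3 + ncol(rot_ax)
    P <- matrix(0, 3 * na, nd)
    for (a in 1:3) P[3 * (idx - 1) + a, a] <- 1
    if (ncol(rot_ax) > 0) {
      for (b in seq_len(ncol(rot_ax))) {
        n <- rot_ax[, b]
        for (ii in seq_along(idx)) {
          P[(3 * (idx[ii] - 1) + 1):(3 * idx[ii]), 3 + b] <-
            .cross3(n, rho[ii, ])
        }
      }
    }
    Pmat <- cbind(Pmat, P)
    tmass <- c(tmass, rep(info$mass, 3), moments)
    labels <- c(labels, paste0("u", u, c("tx", "ty", "tz")),
                if (ncol(rot_ax)) paste0("u", u, "r", seq_len(ncol(rot_ax))))
    # gradient correction on the librational block: for rotation vector w,
    # dr_i = w x rho + 0.5 w x (w x rho); second-order term couples to the
    # residual atomic forces.
    cb <- matrix(0, nd, nd)
    if (ncol(rot_ax) > 0) {
      gi <- g[idx, , drop = FALSE]
      for (a in seq_len(ncol(rot_ax))) for (b in seq_len(ncol(rot_ax))) {
        nA <- rot_ax[, a]; nB <- rot_ax[, b]
        s <- 0
        for (ii in seq_along(idx)) {
          d2r <- 0.5 * (.cross3(nA, .cross3(nB, rho[ii, ])) +
                          .cross3(nB, .cross3(nA, rho[ii, ])))
          s <- s + sum(gi[ii, ] * d2r)
        }
        cb[3 + a, 3 + b] <- s
      }
      # net torque magnitude for the stationarity warning
      tau <- colSums(t(apply(cbind(rho, gi), 1, function(z)
        .cross3(z[1:3], z[4:6]))))
      maxg <- max(maxg, max(abs(tau)))
    }
    maxg <- max(maxg, max(abs(colSums(g[idx, , drop = FALSE]))))
    corr_blocks[[u]] <- cb
    dofs[[u]] <- nd
  }
  ctx$P <- Pmat
  ctx$tmass <- tmass
  ctx$dof_labels <- labels
  ctx$ndof <- length(tmass)
  nd_all <- unlist(dofs)
  corr <- matrix(0, ctx$ndof, ctx$ndof)
  off <- 0
  for (u in seq_len(M)) {
    rng <- (off + 1):(off + nd_all[u])
    corr[rng, rng] <- corr_blocks[[u]]
    off <- off + nd_all[u]
  }
  ctx$corr <- corr
  ctx$gradient_scale <- maxg
  if (!quiet && maxg > warn_tol) {
    warning(sprintf(
      "crystal is not at a stationary point (max force/torque %.3g); phonon frequencies may be imaginary",
      maxg), call. = FALSE)
  }
  ctx
}

# Mass-weighted rigid-body dynamical matrix at fractional k (Hermitian,
# eigenvalues in kJ mol^-1 amu^-1 A^-2; frequencies via freq_to_cm1).
.dyn_k <- function(ctx, kfrac) {
  na <- ctx$na
  kcart <- drop(as.numeric(kfrac) %*% ctx$B)
  D <- matrix(0 + 0i, 3 * na, 3 * na)
  fc <- ctx$fc
  if (length(fc$i)) {
    kr <- drop(fc$Rl %*% kcart)
    re <- rowsum(-fc$H * cos(kr), group = ctx$key_off)
    im <- rowsum(-fc$H * sin(kr), group = ctx$key_off)
    keys <- as.integer(rownames(re))
    for (t in seq_along(keys)) {
      i <- (keys[t] - 1L) %/% na + 1L
      j <- keys[t] - (i - 1L) * na
      D[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <-
        D[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] +
        matrix(re[t, ] + 1i * im[t, ], 3, 3)
    }
    for (t in seq_along(ctx$diag_atoms)) {
      i <- ctx$diag_atoms[t]
      D[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <-
        D[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] + matrix(ctx$diagH[t, ], 3, 3)
    }
  }
  if (!is.null(ctx$ew)) {
    D <- D + .recip_dyn(ctx, kcart) + ctx$recip_self
  }
  C <- t(Conj(ctx$P)) %*% D %*% ctx$P + ctx$corr
  w <- 1 / sqrt(ctx$tmass)
  C <- C * outer(w, w)
  (C + t(Conj(C))) / 2
}

#' Rigid-body dynamical matrix at one k-point
#'
#' Builds the mass-weighted rigid-body (translations + librations)
#' dynamical matrix from analytic second derivatives of the intermolecular
#' energy, with Ewald handling of the point-charge electrostatics.
#' Eigenvalues are squared frequencies; convert with
#' `physical_constants()$freq_to_cm1 * sqrt(lambda)`.
#'
#' @param crystal A `crystal` object (should be at a stationary point; a
#'   warning is emitted otherwise and the calculation proceeds).
#' @param ff A `forcefield` object.
#' @param k Fractional wavevector (3-vector, units of the reciprocal cell).
#' @return Hermitian complex matrix of dimension `sum(dof per rigid unit)`,
#'   with attributes `dof_labels` and `masses`.
#' @export
dynamical_matrix <- function(crystal, ff, k = c(0, 0, 0)) {
  ctx <- .dyn_context(crystal, ff)
  Dm <- .dyn_k(ctx, k)
  attr(Dm, "dof_labels") <- ctx$dof_labels
  attr(Dm, "masses") <- ctx$tmass
  Dm
}

# signed frequency in cm^-1 from an eigenvalue
.signed_freq <- function(lambda) {
  sign(lambda) * .const$freq_to_cm1 * sqrt(abs(lambda))
}

#' Sample the phonon spectrum on a uniform k-grid
#'
#' Frequencies are computed on a Gamma-centred uniform grid. At every
#' k-point the three lowest branches are classified as acoustic; they are
#' represented by a Debye model whose sound velocity is fitted on the
#' innermost sampled k-shell and whose cutoff places exactly 3 modes per
#' primitive cell. All remaining (optic) branches enter the density of
#' states directly (optionally KDE-smoothed). The three Gamma-point zeros
#' are excluded, so the optic weight integrates to `ndof - 3` per cell.
#'
#' @param crystal A stable `crystal` at its lattice-energy minimum.
#' @param ff A `forcefield` object.
#' @param grid Integer 3-vector of grid divisions (default `c(4,4,4)`).
#' @param bandwidth Gaussian KDE bandwidth in cm^-1 stored with the
#'   spectrum (default 3).
#' @param allow_imaginary If `FALSE` (default) any imaginary frequency
#'   (reported as negative, below -0.5 cm^-1) raises an instability error;
#'   if `TRUE` they are kept for diagnostics.
#' @return Object of class `phonon_spectrum`: k-points, weights, sorted
#'   frequencies per k (cm^-1), Debye velocity and cutoff, optic mode list,
#'   cell metadata and the lattice energy per molecule.
#' @export
sample_spectrum <- function(crystal, ff, grid = c(4, 4, 4), bandwidth = 3,
                            allow_imaginary = FALSE) {
  grid <- as.integer(grid)
  if (any(grid < 1)) stop_value("grid divisions must be >= 1")
  ctx <- .dyn_context(crystal, ff)
  kfrac <- as.matrix(expand.grid(
    (0:(grid[1] - 1)) / grid[1],
    (0:(grid[2] - 1)) / grid[2],
    (0:(grid[3] - 1)) / grid[3]))
  kfrac <- kfrac - round(kfrac)          # map into (-1/2, 1/2]
  nk <- nrow(kfrac)
  wk <- rep(1 / nk, nk)
  freqs <- vector("list", nk)
  is_gamma <- rowSums(abs(kfrac)) < 1e-12
  for (t in seq_len(nk)) {
    lam <- eigen(.dyn_k(ctx, kfrac[t, ]), symmetric = TRUE,
                 only.values = TRUE)$values
    freqs[[t]] <- sort(.signed_freq(lam))
  }
  ndof <- ctx$ndof
  # instability screen: at Gamma ignore the three acoustic zeros
  for (t in seq_len(nk)) {
    fr <- freqs[[t]]
    if (is_gamma[t]) fr <- fr[order(abs(fr))][-(1:3)]
    if (length(fr) && min(fr) < -0.5 && !allow_imaginary) {
      stop_instability(sprintf(
        "imaginary phonon frequency %.2f cm^-1 at k = (%.3f, %.3f, %.3f)",
        min(fr), kfrac[t, 1], kfrac[t, 2], kfrac[t, 3]))
    }
  }
  # Debye fit on the innermost shell
  kcart <- kfrac %*% ctx$B
  kn <- sqrt(rowSums(kcart^2))
  debye_v <- NA_real_; omega_d <- NA_real_
  if (any(kn > 1e-12)) {
    kmin <- min(kn[kn > 1e-12])
    shell <- which(abs(kn - kmin) < 1e-8 * max(1, kmin))
    inv3 <- 0
    for (t in shell) {
      ac <- freqs[[t]][1:3]
      if (any(ac <= 0)) ac[ac <= 0] <- NA
      inv3 <- inv3 + sum((ac / kn[t])^-3, na.rm = TRUE)
    }
    debye_v <- (3 * length(shell) / inv3)^(1 / 3)   # cm^-1 * Angstrom
    omega_d <- debye_v * (6 * pi^2 / ctx$V)^(1 / 3)
  }
  # optic modes: drop the 3 lowest everywhere (acoustic), plus the Gamma
  # zeros which are the acoustic modes themselves
  optic_w <- c(); optic_f <- c()
  for (t in seq_len(nk)) {
    fr <- freqs[[t]]
    fr <- if (is_gamma[t]) fr[order(abs(fr))][-(1:3)] else fr[-(1:3)]
    if (length(fr)) {
      optic_f <- c(optic_f, sort(fr))
      optic_w <- c(optic_w, rep(wk[t], length(fr)))
    }
  }
  e_latt <- lattice_energy(crystal, ff)$e_inter
  structure(list(
    kpoints = kfrac, weights = wk, frequencies = freqs,
    debye_velocity = debye_v, omega_debye = omega_d,
    kde_bandwidth = bandwidth, optic_freq = optic_f, optic_weight = optic_w,
    ndof = ndof, n_molecules = n_molecules(ctx$crystal),
    volume = ctx$V, e_latt = e_latt, grid = grid),
    class = "phonon_spectrum")
}

#' @export
print.phonon_spectrum <- function(x, ...) {
  cat(sprintf(
    "phonon spectrum: %d k-points, %d dof/cell, Debye velocity %.2f cm^-1 A, omega_D %.1f cm^-1\n",
    nrow(x$kpoints), x$ndof, x$debye_velocity, x$omega_debye))
  invisible(x)
}

#' Gaussian kernel density estimate of the optic density of states
#'
#' Places a Gaussian of the stated bandwidth on every sampled optic
#' frequency, weighted by k-point weight, normalized so that the integral
#' equals the optic mode count per primitive cell.
#'
#' @param spectrum A `phonon_spectrum`.
#' @param bandwidth Kernel standard deviation in cm^-1 (default: the
#'   spectrum's stored bandwidth).
#' @param n Number of grid points.
#' @return data.frame with columns `omega` (cm^-1) and `g` (modes per
#'   cm^-1 per cell).
#' @export
dos_kde <- function(spectrum, bandwidth = NULL, n = 2048) {
  bw <- bandwidth %||% spectrum$kde_bandwidth
  if (bw <= 0) stop_value("KDE bandwidth must be positive")
  f <- spectrum$optic_freq
  if (length(f) == 0) stop_value("spectrum has no optic modes")
  w <- spectrum$optic_weight
  lo <- min(f) - 5 * bw; hi <- max(f) + 5 * bw
  om <- seq(lo, hi, length.out = n)
  g <- numeric(n)
  for (m in seq_along(f)) {
    g <- g + w[m] * dnorm(om, mean = f[m], sd = bw)
  }
  data.frame(omega = om, g = g)
}

# per-mode harmonic thermodynamics (omega in cm^-1, vectorized)
.mode_fvib <- function(omega, T) {
  e <- omega * .const$cm1_to_kjmol
  if (T <= 0) return(e / 2)
  x <- e / (.const$kB * T)
  e / 2 + .const$kB * T * log1p(-exp(-x))
}
.mode_entropy <- function(omega, T) {
  if (T <= 0) return(0 * omega)
  e <- omega * .const$cm1_to_kjmol
  x <- e / (.const$kB * T)
  ex <- exp(-x)
  .const$kB * (x * ex / (1 - ex) - log1p(-ex))
}
.mode_cv <- function(omega, T) {
  if (T <= 0) return(0 * omega)
  e <- omega * .const$cm1_to_kjmol
  x <- e / (.const$kB * T)
  ex <- exp(-x)
  .const$kB * x^2 * ex / (1 - ex)^2
}

.gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}
.phonon_cache <- new.env(parent = emptyenv())

# Debye acoustic integral of a per-mode function: 3 modes per cell with
# g(omega) = 9 omega^2 / omega_D^3.
.debye_integral <- function(omega_d, T, modefun) {
  if (is.na(omega_d) || omega_d <= 0) return(0)
  if (is.null(.phonon_cache$gl64)) .phonon_cache$gl64 <- .gauss_legendre(64)
  gl <- .phonon_cache$gl64
  om <- 0.5 * omega_d * (gl$nodes + 1)
  w <- 0.5 * omega_d * gl$weights
  sum(w * 9 * om^2 / omega_d^3 * modefun(om, T))
}

#' Harmonic vibrational thermodynamics from a phonon spectrum
#'
#' Per-molecule vibrational free energy, entropy, heat capacity and
#' zero-point energy: the optic branches are integrated over the KDE
#' density of states (or summed discretely for `method = "discrete"`) and
#' the acoustic branches through the analytic Debye density. The entropy is
#' the analytic derivative -dF/dT, not a finite difference.
#'
#' @param spectrum A `phonon_spectrum`.
#' @param T Temperature in K (>= 0).
#' @param method `"kde"` (default) or `"discrete"` for the optic part.
#' @param bandwidth KDE bandwidth override, cm^-1.
#' @return Object of class `thermo_state` with elements `T`, `zpe`,
#'   `f_vib`, `entropy`, `cv` and `a_ha = e_latt + f_vib`, all kJ mol^-1
#'   (entropy and cv in kJ mol^-1 K^-1), per molecule.
#' @export
vib_free_energy <- function(spectrum, T, method = c("kde", "discrete"),
                            bandwidth = NULL) {
  if (T < 0) stop_value("temperature must be non-negative")
  method <- match.arg(method)
  M <- spectrum$n_molecules
  acc <- function(modefun) {
    tot <- .debye_integral(spectrum$omega_debye, T, modefun)
    f <- spectrum$optic_freq; w <- spectrum$optic_weight
    if (length(f)) {
      if (method == "discrete") {
        tot <- tot + sum(w * modefun(f, T))
      } else {
        bw <- bandwidth %||% spectrum$kde_bandwidth
        dg <- dos_kde(spectrum, bandwidth = bw, n = 4096)
        om <- pmax(dg$omega, 1e-3)
        dx <- dg$omega[2] - dg$omega[1]
        tot <- tot + sum(dg$g * modefun(om, T)) * dx
      }
    }
    tot / M
  }
  zpe <- acc(function(om, T) om * .const$cm1_to_kjmol / 2)
  fv <- acc(.mode_fvib)
  s <- acc(.mode_entropy)
  cv <- acc(.mode_cv)
  structure(list(T = T, zpe = zpe, f_vib = fv, entropy = s, cv = cv,
                 e_latt = spectrum$e_latt,
                 a_ha = spectrum$e_latt + fv),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf(
    "T = %.1f K: F_vib = %.4f, ZPE = %.4f, S = %.6f, Cv = %.6f, A_HA = %.4f (kJ/mol per molecule)\n",
    x$T, x$f_vib, x$zpe, x$entropy, x$cv, x$a_ha))
  invisible(x)
}
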