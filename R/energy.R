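# Intermolecular lattice energy: exp-6 repulsion-dispersion (plus optional
# harmonic test springs) summed between whole molecules within a
# centre-of-mass cutoff, and point-charge electrostatics by Ewald summation.
# Intramolecular Coulomb terms are subtracted so that the reported energy is
# purely intermolecular.

#' Atom-atom pair interaction energy
#'
#' Evaluates the exp-6 plus point-charge pair model
#' `A*exp(-B*R) - C/R^6 + k_C*q_i*q_k/R` for one atom pair.
#'
#' @param params List or named vector with elements `A` (kJ mol^-1),
#'   `B` (A^-1) and `C` (kJ mol^-1 A^6).
#' @param q_i,q_k Point charges in elementary charges.
#' @param R Interatomic distance(s), Angstrom; must be positive.
#' @return Energy in kJ mol^-1 (vectorized over `R`).
#' @examples
#' pair_energy(list(A = 1000, B = 3, C = 100), 0, 0, 4)  # ~ -0.0183
#' @export
pair_energy <- function(params, q_i, q_k, R) {
  if (any(R <= 0)) stop_value("pair separation R must be positive")
  params$A * exp(-params$B * R) - params$C / R^6 +
    .const$k_coulomb * q_i * q_k / R
}

# integer image shifts whose lattice vectors can reach within rmax of the
# home cell (per-direction count from the perpendicular cell heights)
.image_shifts <- function(lattice, rmax) {
  V <- det(lattice)
  h <- c(V / sqrt(sum(pracma_cross(lattice[2, ], lattice[3, ])^2)),
         V / sqrt(sum(pracma_cross(lattice[1, ], lattice[3, ])^2)),
         V / sqrt(sum(pracma_cross(lattice[1, ], lattice[2, ])^2)))
  m <- pmax(0L, as.integer(ceiling(rmax / h)))
  as.matrix(expand.grid(l1 = -m[1]:m[1], l2 = -m[2]:m[2], l3 = -m[3]:m[3]))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# unwrapped Cartesian coordinates + molecular centres of mass
.mol_geometry <- function(crystal) {
  M <- n_molecules(crystal)
  na <- nrow(crystal$atoms)
  xyz <- matrix(0, na, 3)
  com <- matrix(0, M, 3)
  for (m in seq_len(M)) {
    u <- crystal$rigid_units[[m]]
    xu <- unwrap_unit(crystal, u)
    xyz[u, ] <- xu
    w <- crystal$atoms$mass[u]
    com[m, ] <- colSums(xu * w) / sum(w)
  }
  list(xyz = xyz, com = com)
}

# Ordered intermolecular short-range terms (every unordered interaction
# appears twice; energies carry weight 1/2). Columns of $rvec point from
# atom i (home cell) to atom j in image Rl.
.sr_terms <- function(crystal, ff, geom = NULL) {
  if (is.null(geom)) geom <- .mol_geometry(crystal)
  M <- n_molecules(crystal)
  com <- geom$com
  diam <- if (M > 1) max(dist(com)) else 0
  sh <- .image_shifts(crystal$lattice, ff$com_cutoff + diam + 1e-9)
  Rl <- sh %*% crystal$lattice
  nimg <- nrow(Rl)
  home <- which(rowSums(abs(sh)) == 0)

  mp <- expand.grid(m = seq_len(M), n = seq_len(M))
  nmp <- nrow(mp)
  dvec2 <- matrix(0, nmp * nimg, 3)
  # displacement com[n] + Rl - com[m] for every (pair, image)
  dcom <- com[mp$n, , drop = FALSE] - com[mp$m, , drop = FALSE]
  dvec2 <- dcom[rep(seq_len(nmp), nimg), , drop = FALSE] +
    Rl[rep(seq_len(nimg), each = nmp), , drop = FALSE]
  keep <- rowSums(dvec2^2) < ff$com_cutoff^2
  selfpair <- rep(mp$m == mp$n, nimg) &
    rep(seq_len(nimg), each = nmp) == home
  keep <- keep & !selfpair
  if (!any(keep)) {
    return(list(i = integer(), j = integer(),
                rvec = matrix(0, 0, 3), Rl = matrix(0, 0, 3)))
  }
  kidx <- which(keep)
  km <- rep(mp$m, nimg)[kidx]
  kn <- rep(mp$n, nimg)[kidx]
  kim <- rep(seq_len(nimg), each = nmp)[kidx]
  dcom <- dvec2[kidx, , drop = FALSE]
  rcom <- sqrt(rowSums(dcom^2))

  units <- crystal$rigid_units
  sizes <- lengths(units)
  npair_atoms <- sizes[km] * sizes[kn]
  # precomputed atom-pair index patterns per (m, n) molecule pair
  pat_i <- vector("list", nmp); pat_j <- vector("list", nmp)
  for (pp in seq_len(nmp)) {
    pat_i[[pp]] <- rep(units[[mp$m[pp]]], times = sizes[mp$n[pp]])
    pat_j[[pp]] <- rep(units[[mp$n[pp]]], each = sizes[mp$m[pp]])
  }
  pid <- (km - 1L) %% M + 1L + (kn - 1L) * M  # row of mp for each triple
  ii <- unlist(pat_i[pid], use.names = FALSE)
  jj <- unlist(pat_j[pid], use.names = FALSE)
  Rl_rep <- Rl[rep(kim, times = npair_atoms), , drop = FALSE]
  rvec <- geom$xyz[jj, , drop = FALSE] + Rl_rep - geom$xyz[ii, , drop = FALSE]
  list(i = ii, j = jj, rvec = rvec, Rl = Rl_rep,
       trip = rep(seq_along(kidx), times = npair_atoms),
       trip_m = km, trip_n = kn, trip_dcom = dcom, trip_rcom = rcom)
}

# quintic smoothstep taper on the molecule COM distance: 1 below
# (cutoff - width), 0 at the cutoff, C2-continuous in between. A sharp
# cutoff (width = 0) makes the energy discontinuous when a molecule pair
# crosses the boundary, which traps gradient-based optimizers.
.taper_S <- function(rcom, cutoff, width) {
  if (width <= 0) return(rep(1, length(rcom)))
  x <- (rcom - (cutoff - width)) / width
  x <- pmin(pmax(x, 0), 1)
  1 - x^3 * (10 - 15 * x + 6 * x^2)
}
.taper_dS <- function(rcom, cutoff, width) {
  if (width <= 0) return(rep(0, length(rcom)))
  x <- (rcom - (cutoff - width)) / width
  inb <- x > 0 & x < 1
  out <- numeric(length(rcom))
  out[inb] <- -30 * x[inb]^2 * (1 - x[inb])^2 / width
  out
}

# Ewald machinery --------------------------------------------------------

.ewald_setup <- function(crystal, accuracy = 1e-10) {
  tol <- max(min(accuracy, 1e-4), 1e-16)
  V <- cell_volume(crystal)
  N <- nrow(crystal$atoms)
  alpha <- (max(N, 2) * pi^3 / V^2)^(1 / 6)
  s <- sqrt(log(1 / tol))
  rcut <- s / alpha
  gcut <- 2 * alpha * s
  B <- 2 * pi * t(solve(crystal$lattice))   # rows are reciprocal vectors
  alen <- sqrt(rowSums(crystal$lattice^2))
  m <- pmax(1L, as.integer(ceiling(gcut * alen / (2 * pi))))
  gidx <- as.matrix(expand.grid(-m[1]:m[1], -m[2]:m[2], -m[3]:m[3]))
  gidx <- gidx[rowSums(abs(gidx)) > 0, , drop = FALSE]
  G <- gidx %*% B
  g2 <- rowSums(G^2)
  sel <- g2 < gcut^2
  list(alpha = alpha, rcut = rcut, gcut = gcut, B = B,
       G = G[sel, , drop = FALSE], g2 = g2[sel], V = V)
}

# Real-space erfc pair terms (ordered, weight 1/2), all atom pairs.
.coul_real_terms <- function(crystal, ew, geom) {
  xyz <- geom$xyz
  na <- nrow(xyz)
  sh <- .image_shifts(crystal$lattice, ew$rcut + 1e-9)
  Rl <- sh %*% crystal$lattice
  nimg <- nrow(Rl)
  home <- which(rowSums(abs(sh)) == 0)
  ap <- expand.grid(i = seq_len(na), j = seq_len(na))
  nap <- nrow(ap)
  dat <- xyz[ap$j, , drop = FALSE] - xyz[ap$i, , drop = FALSE]
  rvec <- dat[rep(seq_len(nap), nimg), , drop = FALSE] +
    Rl[rep(seq_len(nimg), each = nap), , drop = FALSE]
  ii <- rep(ap$i, nimg); jj <- rep(ap$j, nimg)
  Rl_rep <- Rl[rep(seq_len(nimg), each = nap), , drop = FALSE]
  selfterm <- (ii == jj) & (rep(seq_len(nimg), each = nap) == home)
  r2 <- rowSums(rvec^2)
  keep <- !selfterm & r2 < ew$rcut^2
  list(i = ii[keep], j = jj[keep], rvec = rvec[keep, , drop = FALSE],
       Rl = Rl_rep[keep, , drop = FALSE])
}

# Intramolecular bare-Coulomb pairs to subtract (ordered, weight 1/2).
.coul_intra_terms <- function(crystal, geom) {
  ii <- integer(); jj <- integer(); rv <- NULL
  for (u in crystal$rigid_units) {
    if (length(u) < 2) next
    pr <- expand.grid(a = u, b = u)
    pr <- pr[pr$a != pr$b, ]
    ii <- c(ii, pr$a); jj <- c(jj, pr$b)
    rv <- rbind(rv, geom$xyz[pr$b, , drop = FALSE] -
                  geom$xyz[pr$a, , drop = FALSE])
  }
  if (is.null(rv)) rv <- matrix(0, 0, 3)
  list(i = ii, j = jj, rvec = rv, Rl = matrix(0, length(ii), 3))
}

#' Ewald electrostatic energy of a point-charge crystal
#'
#' Full charge-charge lattice sum (real, reciprocal and self terms) for a
#' charge-neutral cell. Includes all atom pairs (intramolecular ones too);
#' [lattice_energy()] subtracts the intramolecular part.
#'
#' @param crystal A `crystal` object.
#' @param charges Optional replacement charge vector (e); defaults to the
#'   charges stored on the atoms.
#' @param accuracy Relative truncation tolerance of the sums.
#' @param alpha Optional override of the Ewald splitting parameter (A^-1),
#'   used to verify splitting-independence.
#' @return Electrostatic energy per unit cell, kJ mol^-1.
#' @export
ewald_energy <- function(crystal, charges = NULL, accuracy = 1e-10,
                         alpha = NULL) {
  q <- if (is.null(charges)) crystal$atoms$charge else charges
  if (abs(sum(q)) > 1e-8) stop_value("Ewald summation requires a neutral cell")
  if (all(abs(q) < 1e-14)) return(0)
  geom <- .mol_geometry(crystal)
  ew <- .ewald_setup(crystal, accuracy)
  if (!is.null(alpha)) {
    s <- sqrt(log(1 / max(min(accuracy, 1e-4), 1e-16)))
    ew$alpha <- alpha; ew$rcut <- s / alpha; ew$gcut <- 2 * alpha * s
    B <- ew$B
    alen <- sqrt(rowSums(crystal$lattice^2))
    m <- pmax(1L, as.integer(ceiling(ew$gcut * alen / (2 * pi))))
    gidx <- as.matrix(expand.grid(-m[1]:m[1], -m[2]:m[2], -m[3]:m[3]))
    gidx <- gidx[rowSums(abs(gidx)) > 0, , drop = FALSE]
    G <- gidx %*% B
    g2 <- rowSums(G^2)
    sel <- g2 < ew$gcut^2
    ew$G <- G[sel, , drop = FALSE]; ew$g2 <- g2[sel]
  }
  ct <- .coul_real_terms(crystal, ew, geom)
  r <- sqrt(rowSums(ct$rvec^2))
  if (any(r < 1e-8)) stop_geometry("coincident point charges")
  e_real <- 0.5 * sum(q[ct$i] * q[ct$j] * erfc_(ew$alpha * r) / r)
  phase <- geom$xyz %*% t(ew$G)             # n_atoms x nG
  Sre <- colSums(q * cos(phase)); Sim <- colSums(q * sin(phase))
  fg <- exp(-ew$g2 / (4 * ew$alpha^2)) / ew$g2
  e_rec <- (2 * pi / ew$V) * sum(fg * (Sre^2 + Sim^2))
  e_self <- -ew$alpha / sqrt(pi) * sum(q^2)
  .const$k_coulomb * (e_real + e_rec + e_self)
}

erfc_ <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

# exp-6 / spring energy from an ordered term list (weight 1/2 applied,
# molecule-pair taper weights included)
.sr_energy <- function(crystal, ff, terms) {
  if (length(terms$i) == 0) return(c(rep_disp = 0, spring = 0))
  r <- sqrt(rowSums(terms$rvec^2))
  ti <- crystal$atoms$ff_type[terms$i]
  tj <- crystal$atoms$ff_type[terms$j]
  S <- .taper_S(terms$trip_rcom, ff$com_cutoff, ff$taper %||% 1)[terms$trip]
  p <- ff_pair_params(ff, ti, tj)
  e_rd <- 0.5 * sum(S * (p[, "A"] * exp(-p[, "B"] * r) - p[, "C"] / r^6))
  e_sp <- 0
  if (!is.null(ff$springs)) {
    s <- ff_spring_params(ff, ti, tj)
    act <- s[, "kappa"] > 0 & r < s[, "rcut"]
    if (any(act)) {
      e_sp <- 0.5 * sum(S[act] * 0.5 * s[act, "kappa"] *
                          (r[act] - s[act, "r0"])^2)
    }
  }
  c(rep_disp = e_rd, spring = e_sp)
}

#' Intermolecular lattice energy of a crystal
#'
#' Evaluates the atom-atom model: exp-6 repulsion-dispersion (and any
#' harmonic test springs) summed between whole molecules whose centres of
#' mass are closer than the force field's `com_cutoff`, plus point-charge
#' electrostatics by Ewald summation with the intramolecular Coulomb part
#' removed. All values are normalized per molecule.
#'
#' @param crystal A `crystal` object with rigid units defined.
#' @param ff A `forcefield` object resolving every `ff_type` present.
#' @param pressure Applied external pressure in GPa (enters only the
#'   `pv_term`).
#' @return List of class `energy_breakdown` with elements `e_rep_disp`,
#'   `e_elec`, `e_inter` (their sum) and `pv_term`, all kJ mol^-1 per
#'   molecule.
#' @export
lattice_energy <- function(crystal, ff, pressure = 0) {
  geom <- .mol_geometry(crystal)
  M <- n_molecules(crystal)
  terms <- .sr_terms(crystal, ff, geom)
  if (length(terms$i)) {
    r2 <- rowSums(terms$rvec^2)
    if (any(r2 < 0.01)) {
      stop_geometry(sprintf(
        "overlapping atoms: intermolecular contact %.4f A < 0.1 A",
        sqrt(min(r2))))
    }
  }
  esr <- .sr_energy(crystal, ff, terms)
  q <- crystal$atoms$charge
  e_elec <- 0
  if (any(abs(q) > 1e-14)) {
    e_elec <- ewald_energy(crystal, accuracy = ff$ewald_accuracy)
    it <- .coul_intra_terms(crystal, geom)
    if (length(it$i)) {
      r <- sqrt(rowSums(it$rvec^2))
      e_elec <- e_elec - 0.5 * sum(.const$k_coulomb * q[it$i] * q[it$j] / r)
    }
  }
  e_rd <- unname(esr["rep_disp"] + esr["spring"])
  out <- list(
    e_rep_disp = e_rd / M,
    e_elec = e_elec / M,
    e_inter = (e_rd + e_elec) / M,
    pv_term = pressure * cell_volume(crystal) * .const$GPaA3_to_kjmol / M)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0(
    "E_inter   = %10.4f kJ/mol per molecule\n",
    "  rep-disp %10.4f\n  elec     %10.4f\n  P*V      %10.4f\n"),
    x$e_inter, x$e_rep_disp, x$e_elec, x$pv_term))
  invisible(x)
}

# derivative helpers for pair kernels: return phi' (and phi'') at r --------

.kernel_d <- function(type, par, r, alpha = NULL) {
  switch(type,
    exp6 = {
      d1 <- -par$A * par$B * exp(-par$B * r) + 6 * par$C / r^7
      d2 <- par$A * par$B^2 * exp(-par$B * r) - 42 * par$C / r^8
      list(d1 = d1, d2 = d2)
    },
    spring = {
      list(d1 = par$kappa * (r - par$r0), d2 = par$kappa + 0 * r)
    },
    coul = {
      # s * k_C * qq * erfc(alpha r)/r  (s = +1) or bare 1/r (alpha NULL, s = -1)
      kq <- .const$k_coulomb * par$qq * par$sign
      if (is.null(alpha)) {
        list(d1 = -kq / r^2, d2 = 2 * kq / r^3)
      } else {
        g <- 2 * alpha / sqrt(pi) * exp(-alpha^2 * r^2)
        er <- erfc_(alpha * r)
        d1 <- kq * (-er / r^2 - g / r)
        d2 <- kq * (2 * er / r^3 + 2 * g / r^2 + 2 * alpha^2 * g)
        list(d1 = d1, d2 = d2)
      }
    })
}

# Analytic Cartesian gradient of the intermolecular energy per cell.
# Rows: atoms; columns x, y, z (kJ mol^-1 A^-1).
atomic_gradient <- function(crystal, ff) {
  geom <- .mol_geometry(crystal)
  na <- nrow(crystal$atoms)
  g <- matrix(0, na, 3)
  q <- crystal$atoms$charge

  add_pair_gradient <- function(terms, d1) {
    # ordered terms, weight 1/2; rvec points i -> j
    r <- sqrt(rowSums(terms$rvec^2))
    coef <- 0.5 * d1 / r
    gx <- terms$rvec * coef
    for (a in 1:3) {
      g[, a] <<- g[, a] +
        unname(tapply(gx[, a], factor(terms$j, levels = seq_len(na)), sum,
                      default = 0)) -
        unname(tapply(gx[, a], factor(terms$i, levels = seq_len(na)), sum,
                      default = 0))
    }
  }

  terms <- .sr_terms(crystal, ff, geom)
  if (length(terms$i)) {
    r <- sqrt(rowSums(terms$rvec^2))
    ti <- crystal$atoms$ff_type[terms$i]
    tj <- crystal$atoms$ff_type[terms$j]
    p <- ff_pair_params(ff, ti, tj)
    kd <- .kernel_d("exp6", list(A = p[, "A"], B = p[, "B"], C = p[, "C"]), r)
    d1 <- kd$d1
    phi <- p[, "A"] * exp(-p[, "B"] * r) - p[, "C"] / r^6
    if (!is.null(ff$springs)) {
      s <- ff_spring_params(ff, ti, tj)
      act <- s[, "kappa"] > 0 & r < s[, "rcut"]
      if (any(act)) {
        d1[act] <- d1[act] + s[act, "kappa"] * (r[act] - s[act, "r0"])
        phi[act] <- phi[act] +
          0.5 * s[act, "kappa"] * (r[act] - s[act, "r0"])^2
      }
    }
    wtap <- ff$taper %||% 1
    S <- .taper_S(terms$trip_rcom, ff$com_cutoff, wtap)
    add_pair_gradient(terms, S[terms$trip] * d1)
    # taper derivative: the switch acts on the molecule COM distance, so
    # every atom of the pair carries a mass-weighted share
    dS <- .taper_dS(terms$trip_rcom, ff$com_cutoff, wtap)
    intap <- which(abs(dS) > 0)
    if (length(intap)) {
      phisum <- rowsum(phi, group = terms$trip)
      tripids <- as.integer(rownames(phisum))
      umass <- vapply(crystal$rigid_units,
                      function(u) sum(crystal$atoms$mass[u]), 1)
      for (t in intap) {
        row <- match(t, tripids)
        if (is.na(row)) next
        w3 <- 0.5 * dS[t] * phisum[row]
        rhat <- terms$trip_dcom[t, ] / terms$trip_rcom[t]
        m_id <- terms$trip_m[t]; n_id <- terms$trip_n[t]
        im <- crystal$rigid_units[[m_id]]
        jn <- crystal$rigid_units[[n_id]]
        g[im, ] <- g[im, ] - outer(crystal$atoms$mass[im] / umass[m_id],
                                   w3 * rhat)
        g[jn, ] <- g[jn, ] + outer(crystal$atoms$mass[jn] / umass[n_id],
                                   w3 * rhat)
      }
    }
  }

  if (any(abs(q) > 1e-14)) {
    ew <- .ewald_setup(crystal, ff$ewald_accuracy)
    ct <- .coul_real_terms(crystal, ew, geom)
    if (length(ct$i)) {
      r <- sqrt(rowSums(ct$rvec^2))
      kd <- .kernel_d("coul", list(qq = q[ct$i] * q[ct$j], sign = 1), r,
                      alpha = ew$alpha)
      add_pair_gradient(ct, kd$d1)
    }
    # reciprocal part
    phase <- geom$xyz %*% t(ew$G)
    cp <- cos(phase); sp <- sin(phase)
    Sre <- colSums(q * cp); Sim <- colSums(q * sp)
    fg <- exp(-ew$g2 / (4 * ew$alpha^2)) / ew$g2
    # dE/dr_i = kC (4 pi / V) q_i sum_G f(G) G * Im(conj(S) e^{iG r_i})
    # Im(conj(S) e^{iG r_i}) = Sre*sp - Sim*cp
    w <- sweep(sp, 2, Sre, "*") - sweep(cp, 2, Sim, "*")   # n_atoms x nG
    pref <- .const$k_coulomb * 4 * pi / ew$V
    g <- g - pref * q * (sweep(w, 2, fg, "*") %*% ew$G)
    # intramolecular bare-Coulomb subtraction
    it <- .coul_intra_terms(crystal, geom)
    if (length(it$i)) {
      r <- sqrt(rowSums(it$rvec^2))
      kd <- .kernel_d("coul", list(qq = q[it$i] * q[it$j], sign = -1), r)
      add_pair_gradient(it, kd$d1)
    }
  }
  g
}
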