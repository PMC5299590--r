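# minimal hand-built spectrum (optic modes only, no Debye term)
fake_spectrum <- function(freqs, weights = rep(1, length(freqs)),
                          bandwidth = 3) {
  structure(list(kpoints = matrix(0, 1, 3), weights = 1,
                 frequencies = list(freqs), debye_velocity = NA_real_,
                 omega_debye = NA_real_, kde_bandwidth = bandwidth,
                 optic_freq = freqs, optic_weight = weights,
                 ndof = length(freqs) + 3, n_molecules = 1,
                 volume = 100, e_latt = 0, grid = c(1L, 1L, 1L)),
            class = "phonon_spectrum")
}

test_that("bead-spring chain reproduces the analytic dispersion exactly", {
  fx <- fx_chain()
  sp <- sample_spectrum(fx$crystal, fx$ff, grid = fx$grid)
  for (t in seq_len(nrow(sp$kpoints))) {
    k <- sp$kpoints[t, 1]
    if (abs(k) < 1e-12) next
    want <- unname(fx$oracle$dispersion(k))
    got <- unname(sp$frequencies[[t]])
    expect_equal(got, rep(want, 3), tolerance = 1e-3)
  }
  # Debye velocity equals the acoustic slope a*sqrt(kappa/m)
  expect_equal(sp$debye_velocity, fx$oracle$debye_velocity, tolerance = 0.02)
})

test_that("time reversal: omega(k) = omega(-k)", {
  fx <- fx_dia("beta")
  for (k in list(c(0.3, 0.1, 0), c(0.2, 0.25, 0.4))) {
    Dp <- suppressWarnings(dynamical_matrix(fx$crystal, fx$ff, k))
    Dm <- suppressWarnings(dynamical_matrix(fx$crystal, fx$ff, -k))
    expect_equal(dyn_freqs(Dp), dyn_freqs(Dm), tolerance = 1e-9)
  }
})

test_that("Gamma dynamical matrix matches a numerical rigid-body Hessian", {
  # off-minimum charged diatomic crystal with a sharp cutoff so that the
  # comparison against numerical second derivatives is exact
  q <- 0.15
  ff <- forcefield(
    types = data.frame(label = c("C1", "O1"), element = c("C", "O"),
                       mass = c(12.011, 15.999), charge = c(q, -q)),
    pairs = data.frame(t1 = c("C1", "C1", "O1"), t2 = c("C1", "O1", "O1"),
                       A = c(1.5e5, 2e5, 2.5e5), B = c(3.6, 3.7, 3.8),
                       C = c(2000, 2200, 2400)),
    com_cutoff = 15, taper = 0)
  cr <- crystal(cellpar_to_lattice(4.2, 4.2, 4.0, 90, 90, 90),
                data.frame(element = c("C", "O", "C", "O"),
                           x = c(0.1, 0.1, 0.6, 0.6),
                           y = c(0.1, 0.1, 0.6, 0.6),
                           z = c(0.10, 0.38, 0.60, 0.32),
                           charge = c(q, -q, q, -q),
                           ff_type = c("C1", "O1", "C1", "O1")),
                rigid_units = list(1:2, 3:4))
  Dm <- suppressWarnings(dynamical_matrix(cr, ff, c(0, 0, 0)))
  expect_lt(max(abs(Im(Dm))), 1e-10)       # Hermitian and real at Gamma
  # numerical rigid-body Hessian over COM translations + rotation vectors
  geom <- polyphonon:::.mol_geometry(cr)
  Ef <- function(cc) lattice_energy(cc, ff)$e_inter * 2
  rigid_E <- function(p) {
    cc <- cr
    for (u in 1:2) {
      idx <- cr$rigid_units[[u]]
      info <- rigid_unit_info(cr, u)
      t_ <- p[(u - 1) * 6 + 1:3]; w_ <- p[(u - 1) * 6 + 4:6]
      R <- polyphonon:::.rodrigues(w_)
      rel <- sweep(geom$xyz[idx, ], 2, info$com)
      newx <- sweep(rel %*% t(R), 2, info$com + t_, "+")
      cc$atoms[idx, c("x", "y", "z")] <- newx %*% solve(cr$lattice)
    }
    Ef(cc)
  }
  h <- 1e-4
  Hr <- matrix(0, 12, 12)
  for (i in 1:12) for (j in i:12) {
    pp <- numeric(12); pp[i] <- pp[i] + h; pp[j] <- pp[j] + h
    pm <- numeric(12); pm[i] <- pm[i] + h; pm[j] <- pm[j] - h
    mp <- numeric(12); mp[i] <- mp[i] - h; mp[j] <- mp[j] + h
    mm <- numeric(12); mm[i] <- mm[i] - h; mm[j] <- mm[j] - h
    Hr[i, j] <- Hr[j, i] <-
      (rigid_E(pp) - rigid_E(pm) - rigid_E(mp) + rigid_E(mm)) / (4 * h^2)
  }
  Tm <- matrix(0, 12, 12)
  for (u in 1:2) {
    info <- rigid_unit_info(cr, u)
    Tm[(u - 1) * 6 + 1:3, (u - 1) * 6 + 1:3] <- diag(3) * info$mass
    Tm[(u - 1) * 6 + 4:6, (u - 1) * 6 + 4:6] <- info$inertia_tensor
  }
  eT <- eigen(Tm, symmetric = TRUE)
  keep <- eT$values > 1e-6 * max(eT$values)
  W <- eT$vectors[, keep] %*% diag(1 / sqrt(eT$values[keep]))
  ev_num <- sort(eigen(t(W) %*% Hr %*% W, symmetric = TRUE,
                       only.values = TRUE)$values)
  ev_our <- sort(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev_our, ev_num, tolerance = 1e-4)
})

test_that("supercell folding: primitive {Gamma, X} equals 2x1x1 at Gamma", {
  fx <- fx_dia("beta")
  ev_p <- sort(c(
    eigen(suppressWarnings(dynamical_matrix(fx$crystal, fx$ff, c(0, 0, 0))),
          symmetric = TRUE, only.values = TRUE)$values,
    eigen(suppressWarnings(dynamical_matrix(fx$crystal, fx$ff, c(.5, 0, 0))),
          symmetric = TRUE, only.values = TRUE)$values))
  sup <- make_supercell(fx$crystal, 2, 1, 1)
  ev_s <- sort(eigen(suppressWarnings(dynamical_matrix(sup, fx$ff,
                                                       c(0, 0, 0))),
                     symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev_p, ev_s, tolerance = 1e-6)
})

test_that("Gamma-only grid gives a spectrum without a Debye term", {
  fx <- fx_dia("alpha")
  sp <- sample_spectrum(fx$crystal, fx$ff, grid = c(1, 1, 1))
  expect_equal(nrow(sp$kpoints), 1)
  expect_true(is.na(sp$debye_velocity))
  # optic weight integrates to ndof - 3
  expect_equal(sum(sp$optic_weight), sp$ndof - 3)
})

test_that("KDE density of states is normalized to the optic mode count", {
  sp1 <- fake_spectrum(100)
  dg <- dos_kde(sp1, bandwidth = 5)
  dx <- dg$omega[2] - dg$omega[1]
  expect_equal(sum(dg$g) * dx, 1, tolerance = 1e-6)
  expect_equal(dg$omega[which.max(dg$g)], 100, tolerance = 0.1)
  sp2 <- fake_spectrum(c(80, 120))
  dg2 <- dos_kde(sp2, bandwidth = 5)
  expect_equal(sum(dg2$g) * (dg2$omega[2] - dg2$omega[1]), 2,
               tolerance = 1e-6)
  expect_error(dos_kde(sp1, bandwidth = 0), class = "polyphonon_value_error")
})

test_that("per-mode free energy matches closed forms", {
  cst <- physical_constants()
  # T = 0: F_vib equals the zero-point energy exactly
  sp <- fake_spectrum(c(50, 120))
  ts0 <- vib_free_energy(sp, 0, method = "discrete")
  expect_equal(ts0$f_vib, ts0$zpe, tolerance = 1e-12)
  expect_equal(ts0$zpe, sum(c(50, 120)) * cst$cm1_to_kjmol / 2,
               tolerance = 1e-12)
  expect_equal(ts0$entropy, 0)
  # one mode with hbar*omega/kB*T = 1: F/(hbar omega) = 0.5 + ln(1 - e^-1)
  om <- 100
  Tq <- om * cst$cm1_to_kjmol / cst$kB
  ts <- vib_free_energy(fake_spectrum(om), Tq, method = "discrete")
  expect_equal(ts$f_vib / (om * cst$cm1_to_kjmol), 0.5 + log(1 - exp(-1)),
               tolerance = 1e-10)
  expect_error(vib_free_energy(sp, -5), class = "polyphonon_value_error")
})

test_that("analytic entropy equals -dF/dT and Cv reaches equipartition", {
  fx <- fx_fcc()
  sp <- memo("fcc_spectrum", sample_spectrum(fx$crystal, fx$ff))
  for (Tt in c(100, 300)) {
    ts <- vib_free_energy(sp, Tt)
    fp <- vib_free_energy(sp, Tt + 0.1)$f_vib
    fm <- vib_free_energy(sp, Tt - 0.1)$f_vib
    expect_equal(ts$entropy, -(fp - fm) / 0.2, tolerance = 1e-6)
  }
  # classical limit: Cv -> kB per mode when hbar*omega << kB*T
  cst <- physical_constants()
  Thot <- 10 * cst$cm1_to_kjmol / cst$kB / 0.05
  tsh <- vib_free_energy(fake_spectrum(10), Thot, method = "discrete")
  expect_equal(tsh$cv, cst$kB, tolerance = 0.01)
})

test_that("KDE free energy converges to the discrete sum and in the grid", {
  fx <- fx_fcc()
  sp <- memo("fcc_spectrum", sample_spectrum(fx$crystal, fx$ff))
  fd <- vib_free_energy(sp, 300, method = "discrete")$f_vib
  fk <- vib_free_energy(sp, 300, method = "kde", bandwidth = 0.2)$f_vib
  expect_equal(fk, fd, tolerance = 0.01)
  sp6 <- sample_spectrum(fx$crystal, fx$ff, grid = c(6, 6, 6))
  f4 <- vib_free_energy(sp, 300)$f_vib
  f6 <- vib_free_energy(sp6, 300)$f_vib
  expect_lt(abs(f6 - f4), 0.1)
})

test_that("imaginary modes raise an instability error unless allowed", {
  fx <- fx_fcc()
  stretched <- polyphonon:::.isotropic_scale(fx$crystal, 1.5^(1 / 3))
  expect_error(suppressWarnings(sample_spectrum(stretched, fx$ff)),
               class = "polyphonon_instability_error")
  sp <- suppressWarnings(sample_spectrum(stretched, fx$ff,
                                         allow_imaginary = TRUE))
  expect_lt(min(unlist(sp$frequencies)), -0.5)
})
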