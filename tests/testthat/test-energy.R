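test_that("pair_energy evaluates the exp-6 plus Coulomb model", {
  # hand evaluation: 1000 e^-12 - 100/4^6
  expect_equal(pair_energy(list(A = 1000, B = 3, C = 100), 0, 0, 4),
               1000 * exp(-12) - 100 / 4096, tolerance = 1e-12)
  expect_equal(pair_energy(list(A = 1000, B = 3, C = 100), 0, 0, 4),
               -0.01827, tolerance = 1e-3)
  # bare Coulomb at 1 A recovers the molar Coulomb constant
  expect_equal(pair_energy(list(A = 0, B = 1, C = 0), 1, 1, 1),
               1389.3546, tolerance = 1e-4)
  # null interaction at any distance
  expect_equal(pair_energy(list(A = 0, B = 1, C = 0), 0, 0, c(1, 2, 7)),
               c(0, 0, 0))
  expect_error(pair_energy(list(A = 1, B = 1, C = 1), 0, 0, 0),
               class = "polyphonon_value_error")
})

test_that("Ewald summation reproduces the NaCl and CsCl Madelung constants", {
  kc <- physical_constants()$k_coulomb
  nacl <- crystal(diag(3) * 2, data.frame(
    element = rep(c("Na", "Cl"), each = 4),
    x = c(0, .5, .5, 0, .5, 0, 0, .5),
    y = c(0, .5, 0, .5, 0, .5, 0, .5),
    z = c(0, 0, .5, .5, 0, 0, .5, .5),
    charge = rep(c(1, -1), each = 4)))
  mad <- -ewald_energy(nacl) / 4 / kc
  expect_equal(mad, 1.747565, tolerance = 1e-5)
  # independent direct-summation (Evjen) oracle agrees
  expect_equal(mad, evjen_madelung_nacl(8), tolerance = 1e-4)
  cscl <- crystal(diag(3) * 2 / sqrt(3), data.frame(
    element = c("Cs", "Cl"), x = c(0, .5), y = c(0, .5), z = c(0, .5),
    charge = c(1, -1)))
  expect_equal(-ewald_energy(cscl) / kc, 1.762675, tolerance = 1e-5)
})

test_that("Ewald energy is independent of the splitting parameter", {
  nacl <- crystal(diag(3) * 2, data.frame(
    element = rep(c("Na", "Cl"), each = 4),
    x = c(0, .5, .5, 0, .5, 0, 0, .5),
    y = c(0, .5, 0, .5, 0, .5, 0, .5),
    z = c(0, 0, .5, .5, 0, 0, .5, .5),
    charge = rep(c(1, -1), each = 4)))
  e0 <- ewald_energy(nacl)
  e1 <- ewald_energy(nacl, alpha = 1.8)
  e2 <- ewald_energy(nacl, alpha = 3.2)
  expect_equal(e1, e0, tolerance = 1e-6)
  expect_equal(e2, e0, tolerance = 1e-6)
  # all charges zero -> exactly 0
  expect_identical(ewald_energy(nacl, charges = rep(0, 8)), 0)
  # net-charged cell is rejected
  expect_error(ewald_energy(nacl, charges = rep(1, 8)),
               class = "polyphonon_value_error")
})

test_that("an isolated molecule has (almost) no intermolecular energy", {
  fx <- fx_dia("alpha")
  iso <- crystal(diag(3) * 100,
                 data.frame(element = c("C", "O"), x = c(.5, .5),
                            y = c(.5, .5), z = c(.5, .5 + 1.1 / 100),
                            charge = c(0.15, -0.15),
                            ff_type = c("C1", "O1")),
                 rigid_units = list(1:2))
  eb <- lattice_energy(iso, fx$ff)
  expect_lt(abs(eb$e_inter), 1e-3)
})

test_that("lattice energy is invariant to rigid translation and rotation", {
  fx <- fx_dia("beta")
  cr <- fx$crystal
  e0 <- lattice_energy(cr, fx$ff)$e_inter
  # translation of all atoms
  crt <- cr
  crt$atoms[, c("x", "y", "z")] <-
    (crt$atoms[, c("x", "y", "z")] + rep(c(0.2371, 0.111, 0.049), each = 4)) %% 1
  expect_equal(lattice_energy(crt, fx$ff)$e_inter, e0, tolerance = 1e-8)
  # rotation of the whole crystal (lattice and coordinates together)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  crr <- cr
  crr$lattice <- cr$lattice %*% t(R)
  expect_equal(lattice_energy(crr, fx$ff)$e_inter, e0, tolerance = 1e-8)
})

test_that("energy breakdown is consistent and PV term correct", {
  fx <- fx_fcc()
  eb <- lattice_energy(fx$crystal, fx$ff, pressure = 0.5)
  expect_equal(eb$e_inter, eb$e_rep_disp + eb$e_elec, tolerance = 1e-10)
  pv <- 0.5 * cell_volume(fx$crystal) *
    physical_constants()$GPaA3_to_kjmol / n_molecules(fx$crystal)
  expect_equal(eb$pv_term, pv, tolerance = 1e-12)
})

test_that("overlapping molecules raise a geometry error", {
  fx <- fx_fcc()
  cr <- fx$crystal
  cr$atoms$x[2] <- cr$atoms$x[1] + 0.05 / cr$lattice[1, 1]
  cr$atoms$y[2] <- cr$atoms$y[1]
  cr$atoms$z[2] <- cr$atoms$z[1]
  expect_error(lattice_energy(cr, fx$ff),
               class = "polyphonon_geometry_error")
})

test_that("analytic atomic gradient matches central finite differences", {
  fx <- fx_dia("beta")
  cr <- fx$crystal
  # displace slightly off the minimum so the gradient is non-trivial
  cr$atoms$x[1] <- cr$atoms$x[1] + 0.01
  cr$atoms$z[3] <- cr$atoms$z[3] + 0.012
  ga <- polyphonon:::atomic_gradient(cr, fx$ff)
  L <- cr$lattice
  h <- 1e-5
  Ef <- function(cc) lattice_energy(cc, fx$ff)$e_inter * n_molecules(cc)
  for (i in c(1, 3)) for (a in 1:3) {
    dfrac <- solve(t(L), diag(3)[, a] * h)
    cp <- cr; cm <- cr
    cp$atoms[i, c("x", "y", "z")] <- cp$atoms[i, c("x", "y", "z")] + dfrac
    cm$atoms[i, c("x", "y", "z")] <- cm$atoms[i, c("x", "y", "z")] - dfrac
    gn <- (Ef(cp) - Ef(cm)) / (2 * h)
    expect_equal(ga[i, a], gn, tolerance = 1e-5)
  }
})

test_that("force field file round trip and combining rules", {
  fx <- fx_dia("alpha")
  f <- tempfile(fileext = ".txt")
  write_forcefield(fx$ff, f)
  ff2 <- read_forcefield(f)
  expect_equal(ff2$types$charge, fx$ff$types$charge, tolerance = 1e-6)
  expect_equal(ff2$pairs$A, fx$ff$pairs$A, tolerance = 1e-6)
  expect_equal(ff2$com_cutoff, fx$ff$com_cutoff)
  # missing cross pair: combination rule with a warning
  ff3 <- forcefield(
    types = data.frame(label = c("A1", "B1"), element = c("C", "O"),
                       mass = c(12, 16), charge = c(0, 0)),
    pairs = data.frame(t1 = c("A1", "B1"), t2 = c("A1", "B1"),
                       A = c(100, 400), B = c(2, 4), C = c(9, 16)))
  expect_warning(p <- polyphonon:::ff_pair_params(ff3, "A1", "B1"),
                 "combining rules")
  expect_equal(unname(p[1, ]), c(200, 3, 12))  # geometric, arithmetic, geometric
})
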