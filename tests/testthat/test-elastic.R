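test_that("Voigt/Reuss/Hill closed forms", {
  # cubic c11 = 3, c12 = 1, c44 = 1 (isotropic since c11 - c12 = 2 c44)
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- 1; diag(C)[1:3] <- 3; diag(C)[4:6] <- 1
  m <- hill_moduli(C)
  expect_equal(m$k_voigt, 5 / 3, tolerance = 1e-10)
  expect_equal(m$k_reuss, 5 / 3, tolerance = 1e-10)
  expect_equal(m$k_hill, 5 / 3, tolerance = 1e-10)
  expect_equal(m$g_voigt, 1, tolerance = 1e-10)
  expect_equal(m$g_reuss, 1, tolerance = 1e-10)
  expect_equal(m$g_hill, 1, tolerance = 1e-10)
  # identity tensor: K_V = 1/3, G_V = (3 + 9)/15 = 0.8
  mI <- hill_moduli(diag(6))
  expect_equal(mI$k_voigt, 1 / 3, tolerance = 1e-12)
  expect_equal(mI$g_voigt, 0.8, tolerance = 1e-12)
  # indefinite tensor: moduli still reported, with a warning
  Cneg <- diag(c(3, 3, 3, 1, 1, -0.5))
  Cneg[1:3, 1:3][upper.tri(diag(3))] <- 1
  Cneg[1:3, 1:3][lower.tri(diag(3))] <- 1
  expect_warning(mneg <- hill_moduli(Cneg), "not positive definite")
  expect_false(mneg$definite)
})

test_that("bound ordering Reuss <= Hill <= Voigt on computed tensors", {
  for (nm in c("fcc", "dia_alpha")) {
    fx <- if (nm == "fcc") fx_fcc() else fx_dia("alpha")
    ct <- memo(paste0("ct_", nm),
               elastic_tensor(fx$crystal, fx$ff,
                              relax_internal = (nm != "fcc")))
    m <- hill_moduli(ct)
    expect_lte(m$k_reuss, m$k_hill + 1e-9)
    expect_lte(m$k_hill, m$k_voigt + 1e-9)
    expect_lte(m$g_reuss, m$g_hill + 1e-9)
    expect_lte(m$g_hill, m$g_voigt + 1e-9)
    expect_equal(m$k_hill, (m$k_voigt + m$k_reuss) / 2, tolerance = 1e-12)
    # symmetry and positive definiteness at the stable minimum
    expect_lt(max(abs(ct$c - t(ct$c))), 1e-6)
    expect_true(all(eigen(ct$c, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("bulk modulus from the tensor matches a volume scan", {
  fx <- fx_fcc()
  ct <- memo("ct_fcc", elastic_tensor(fx$crystal, fx$ff,
                                      relax_internal = FALSE))
  K <- hill_moduli(ct)$k_voigt
  h <- 0.004
  ee <- vapply(1 + h * (-2:2), function(s) {
    lattice_energy(polyphonon:::.isotropic_scale(fx$crystal, s^(1 / 3)),
                   fx$ff)$e_inter * 4
  }, 1)
  V0 <- cell_volume(fx$crystal)
  d2 <- (-ee[1] + 16 * ee[2] - 30 * ee[3] + 16 * ee[4] - ee[5]) /
    (12 * (h * V0)^2)
  K_scan <- V0 * d2 * physical_constants()$kjmolA3_to_GPa
  expect_equal(K, K_scan, tolerance = 0.02)
})

test_that("the bead-spring crystal is elastically isotropic", {
  # analytic: zero-rest-length springs give c12 = 0 and c11 = 2 c44,
  # i.e. exactly the isotropy condition c11 - c12 = 2 c44
  fx <- fx_chain()
  ct <- elastic_tensor(fx$crystal, fx$ff, relax_internal = FALSE)
  iso_gap <- (ct$c[1, 1] - ct$c[1, 2]) - 2 * ct$c[4, 4]
  expect_lt(abs(iso_gap) / ct$c[1, 1], 0.03)
  # and the closed form c11 = kappa a^2 / V
  kappa <- fx$ff$springs$kappa; a <- fx$crystal$lattice[1, 1]
  c11_exact <- kappa * a^2 / cell_volume(fx$crystal) *
    physical_constants()$kjmolA3_to_GPa
  expect_equal(ct$c[1, 1], c11_exact, tolerance = 1e-3)
})

test_that("rotating the crystal permutes tensor components consistently", {
  fx <- fx_dia("beta")
  ct <- memo("ct_beta_clamped",
             elastic_tensor(fx$crystal, fx$ff, relax_internal = FALSE))
  # rotate 90 degrees about z: x -> y, y -> -x
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rot <- fx$crystal
  rot$lattice <- fx$crystal$lattice %*% t(R)
  ctr <- elastic_tensor(rot, fx$ff, relax_internal = FALSE)
  # 11 <-> 22, 44 <-> 55, 13 <-> 23 under the quarter turn
  expect_equal(ctr$c[1, 1], ct$c[2, 2], tolerance = 1e-4)
  expect_equal(ctr$c[2, 2], ct$c[1, 1], tolerance = 1e-4)
  expect_equal(ctr$c[4, 4], ct$c[5, 5], tolerance = 1e-4)
  expect_equal(ctr$c[5, 5], ct$c[4, 4], tolerance = 1e-4)
  expect_equal(ctr$c[1, 3], ct$c[2, 3], tolerance = 1e-4)
  expect_equal(ctr$c[3, 3], ct$c[3, 3], tolerance = 1e-4)
})

test_that("internal relaxation can only soften the diagonal", {
  fx <- fx_dia("alpha")
  clamped <- memo("ct_alpha_clamped",
                  elastic_tensor(fx$crystal, fx$ff, relax_internal = FALSE))
  relaxed <- memo("ct_dia_alpha",
                  elastic_tensor(fx$crystal, fx$ff, relax_internal = TRUE))
  expect_true(all(diag(relaxed$c) <= diag(clamped$c) + 1e-6))
})

test_that("softening profile reports percentage decreases", {
  # arithmetic of the reporting convention on constructed inputs
  k0 <- 10; kT <- 5
  expect_equal((k0 - kT) / k0 * 100, 50)
  # frozen structure: zero decrease
  fx <- fx_fcc()
  prof <- softening_profile(fx$crystal, list(fx$crystal), fx$ff,
                            relax_internal = FALSE)
  expect_equal(prof$k_decrease_pct[1], 0, tolerance = 1e-8)
  expect_equal(prof$g_decrease_pct[1], 0, tolerance = 1e-8)
})
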