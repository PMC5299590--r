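test_that("cell volume and crystal invariants", {
  cr <- crystal(diag(c(4, 5, 6)),
                data.frame(element = c("C", "O"), x = c(0, 0.2),
                           y = c(0, 1.2), z = c(0, -0.3)))
  expect_equal(cell_volume(cr), 120)
  # fractional coordinates wrapped into [0, 1)
  expect_true(all(as.matrix(cr$atoms[, c("x", "y", "z")]) >= 0))
  expect_true(all(as.matrix(cr$atoms[, c("x", "y", "z")]) < 1))
  expect_error(crystal(-diag(3), data.frame(element = "C", x = 0, y = 0,
                                            z = 0)),
               class = "polyphonon_value_error")
  expect_error(crystal(diag(3), data.frame(element = "C", x = 0, y = 0,
                                           z = 0),
                       rigid_units = list(c(1L, 2L))),
               class = "polyphonon_value_error")
})

test_that("CIF write/read round trip preserves the full atom record", {
  cr <- crystal(cellpar_to_lattice(4, 5, 6, 90, 95, 90),
                data.frame(element = c("C", "O", "H"),
                           x = c(0.1, 0.2, 0.32), y = c(0.15, 0.25, 0.4),
                           z = c(0.3, 0.45, 0.5),
                           charge = c(0.2, -0.35, 0.15),
                           ff_type = c("C1", "O1", "H1")),
                rigid_units = list(1:3))
  f <- tempfile(fileext = ".cif")
  write_cif(cr, f)
  cr2 <- read_cif(f, bond_scale = NULL)
  expect_equal(as.matrix(cr2$atoms[, c("x", "y", "z")]),
               as.matrix(cr$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(cr2$atoms$charge, cr$atoms$charge, tolerance = 1e-6)
  expect_identical(cr2$atoms$ff_type, cr$atoms$ff_type)
  expect_equal(cr2$lattice, cr$lattice, tolerance = 1e-5)
  # second round trip is exact against the first
  f2 <- tempfile(fileext = ".cif")
  write_cif(cr2, f2)
  cr3 <- read_cif(f2, bond_scale = NULL)
  expect_equal(cr3$atoms, cr2$atoms, tolerance = 1e-9)
})

test_that("CIF reader expands symmetry operators to P1", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell_length_a 6.0", "_cell_length_b 6.0", "_cell_length_c 6.0",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "  'x, y, z'",
    "  '-x, -y, z+1/2'",
    "loop_",
    "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.2 0.05"), f)
  cr <- read_cif(f, bond_scale = NULL)
  expect_equal(nrow(cr$atoms), 2)
  expect_equal(sort(cr$atoms$z), c(0.05, 0.55))
  expect_equal(sort(cr$atoms$x), c(0.1, 0.9))
})

test_that("CIF error handling", {
  f <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell_length_b 5", "_cell_length_c 5"), f)
  expect_error(read_cif(f), class = "polyphonon_format_error")
  writeLines(c("data_x", "_cell_length_a 5", "_cell_length_b 5",
               "_cell_length_c 5", "loop_", "_atom_site_label",
               "_atom_site_type_symbol", "_atom_site_fract_x",
               "_atom_site_fract_y", "_atom_site_fract_z",
               "Q1 Qq 0 0 0"), f)
  expect_error(read_cif(f), class = "polyphonon_format_error")
  expect_error(read_cif(tempfile()), class = "polyphonon_format_error")
  cr <- crystal(diag(3) * 4, data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_error(write_cif(list(), tempfile()),
               class = "polyphonon_value_error")
})

test_that("supercell scales atoms and volume and keeps units", {
  fx <- fx_chain()
  cr <- fx$crystal
  expect_identical(make_supercell(cr, 1, 1, 1), cr)
  s2 <- make_supercell(cr, 2, 1, 1)
  expect_equal(nrow(s2$atoms), 2 * nrow(cr$atoms))
  expect_equal(cell_volume(s2), 2 * cell_volume(cr))
  expect_equal(length(s2$rigid_units), 2 * length(cr$rigid_units))
  expect_error(make_supercell(cr, 0, 1, 1), class = "polyphonon_value_error")
})

test_that("supercell commutes with lattice energy per molecule", {
  fx <- fx_fcc()
  e1 <- lattice_energy(fx$crystal, fx$ff)$e_inter
  e8 <- lattice_energy(make_supercell(fx$crystal, 2, 2, 2), fx$ff)$e_inter
  expect_equal(e8, e1, tolerance = 1e-9)
})

test_that("rigid units from the bond graph", {
  # isolated diatomic: one unit of 2 atoms
  cr <- crystal(diag(3) * 20,
                data.frame(element = c("C", "O"), x = c(0.5, 0.5),
                           y = c(0.5, 0.5), z = c(0.5, 0.5 + 1.1 / 20)))
  u <- identify_rigid_units(cr, 1.2)
  expect_length(u, 1)
  expect_setequal(u[[1]], 1:2)
  # two molecules 4 A apart: two units
  cr2 <- crystal(diag(3) * 20,
                 data.frame(element = c("C", "O", "C", "O"),
                            x = c(.5, .5, .7, .7), y = c(.5, .5, .5, .5),
                            z = c(.5, .555, .5, .555)))
  expect_length(identify_rigid_units(cr2, 1.2), 2)
  # bond_scale 0: every atom its own unit
  expect_length(identify_rigid_units(cr2, 0), 4)
  # a chain of bonded atoms through the cell boundary is a polymer
  cr3 <- crystal(diag(c(1.4, 20, 20)),
                 data.frame(element = "C", x = 0, y = 0.5, z = 0.5))
  expect_error(identify_rigid_units(cr3, 1.2),
               class = "polyphonon_polymer_error")
})

test_that("rigid-unit partition is invariant to atom order", {
  at <- data.frame(element = c("C", "O", "C", "O"),
                   x = c(.5, .5, .7, .7), y = c(.5, .5, .5, .5),
                   z = c(.5, .555, .5, .555))
  cr <- crystal(diag(3) * 20, at)
  u1 <- identify_rigid_units(cr, 1.2)
  perm <- c(3, 1, 4, 2)
  cr2 <- crystal(diag(3) * 20, at[perm, ])
  u2 <- identify_rigid_units(cr2, 1.2)
  # map back through the permutation: same partition of the same atoms
  back <- lapply(u2, function(v) as.integer(sort(perm[v])))
  expect_setequal(lapply(u1, sort), back)
})

test_that("rigid_unit_info reports com, inertia and unit quaternion", {
  fx <- fx_dia("alpha")
  info <- rigid_unit_info(fx$crystal, 1)
  expect_equal(sum(info$orientation^2), 1, tolerance = 1e-12)
  ev <- eigen(info$inertia_tensor, symmetric = TRUE)$values
  expect_true(all(ev > -1e-10))          # positive semi-definite
  expect_equal(max(abs(info$inertia_tensor - t(info$inertia_tensor))), 0)
})
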