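test_that("conformer RMSD is zero under rigid motion", {
  X <- matrix(c(0, 0, 0, 1.5, 0, 0, 0.7, 1.2, 0, 0.2, 0.4, 1.1),
              4, 3, byrow = TRUE)
  el <- c("C", "C", "O", "N")
  expect_equal(conformer_rmsd(X, X, ignore_h = FALSE), 0, tolerance = 1e-12)
  th <- 0.8; ph <- 1.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  Y <- sweep(X %*% t(R), 2, c(3.2, -1.1, 0.6), "+")
  expect_equal(conformer_rmsd(X, Y, ignore_h = FALSE), 0, tolerance = 1e-8)
  # hydrogens excluded on request
  Xh <- rbind(X, c(5, 5, 5)); Yh <- rbind(Y, c(-2, 0, 1))
  expect_equal(conformer_rmsd(Xh, Yh, ignore_h = TRUE,
                              elements = c(el, "H")), 0, tolerance = 1e-8)
  expect_error(conformer_rmsd(X, X[1:3, ], ignore_h = FALSE),
               class = "polyphonon_value_error")
})

test_that("superposed RMSD matches a brute-force rotation-grid oracle", {
  X <- matrix(c(0, 0, 0, 1.5, 0, 0, 0.7, 1.2, 0, 0.2, 0.4, 1.1),
              4, 3, byrow = TRUE)
  Y <- X
  Y[2, ] <- Y[2, ] + c(0.5, 0, 0)   # one atom displaced by 0.5 A
  r <- conformer_rmsd(X, Y, ignore_h = FALSE)
  oracle <- rmsd_rotation_grid(X, Y, nang = 24)
  expect_lte(r, oracle + 1e-6)      # Kabsch is the optimum
  expect_equal(r, oracle, tolerance = 0.1)
  expect_lte(r, 0.25)
})

test_that("pair classification sign logic", {
  c1 <- classify_pair(1.0, -0.5)
  expect_true(c1$reranked)
  expect_equal(c1$relationship, "enantiotropic-predicted")
  c2 <- classify_pair(1.0, 2.0)
  expect_false(c2$reranked)
  expect_equal(c2$relationship, "monotropic-predicted")
  expect_equal(c2$curve_shape, "diverging")
  c3 <- classify_pair(1.0, 0.3)
  expect_equal(c3$curve_shape, "converging")
  c4 <- classify_pair(0.004, 0.5, tol = 0.01)
  expect_equal(c4$relationship, "degenerate")
  expect_error(classify_pair(1, 1, tol = -1),
               class = "polyphonon_value_error")
})

test_that("classification is antisymmetric under label swap", {
  set.seed(42)
  for (i in 1:50) {
    d0 <- rnorm(1); dT <- rnorm(1)
    a <- classify_pair(d0, dT)
    b <- classify_pair(-d0, -dT)
    expect_identical(a$relationship, b$relationship)
    expect_identical(a$curve_shape, b$curve_shape)
    expect_identical(a$reranked, b$reranked)
  }
})

test_that("error statistics on the thermal-expansion benchmark table", {
  tab <- alpha_v_table()
  es <- error_stats(data.frame(calc = tab$calc, exp = tab$exp))
  expect_equal(es$mape, 15.0, tolerance = 0.1)
  expect_equal(es$mean_signed, 2.5, tolerance = 0.1)
  expect_equal(es$n, 8)
  # exact agreement gives (0, 0)
  es0 <- error_stats(data.frame(calc = tab$exp, exp = tab$exp))
  expect_equal(es0$mape, 0)
  expect_equal(es0$mean_signed, 0)
  expect_error(error_stats(data.frame(calc = 1, exp = 0)),
               class = "polyphonon_value_error")
})

test_that("mape >= |mean signed error| always", {
  set.seed(7)
  for (i in 1:25) {
    es <- error_stats(data.frame(calc = rnorm(10, 100, 30),
                                 exp = rnorm(10, 100, 30)))
    expect_gte(es$mape, abs(es$mean_signed))
  }
})

test_that("survey counts fractions and distribution summaries", {
  p <- data.frame(
    d_elatt = c(rep(1, 8), 1, 1),
    d_a0 = c(rep(1, 8), 1, 1),
    d_a_tm = c(rep(2, 4), rep(0.5, 4), -1, -2),  # 4 diverging, 2 reranked
    d_qha_ha = rep(0.1, 10))
  s <- survey(p)
  expect_equal(s$n, 10)
  expect_equal(s$frac_reranked, 0.2)
  expect_equal(s$frac_diverging, 0.4)
  # invariant to pair order
  s2 <- survey(p[sample(10), ])
  expect_equal(s2$frac_reranked, s$frac_reranked)
  expect_equal(s2$frac_diverging, s$frac_diverging)
  # identical pairs have zero spread
  s3 <- survey(p[rep(1, 5), ])
  expect_true(all(s3$summary$sd == 0))
})

test_that("synthetic ensembles are seed-deterministic with the stated sd", {
  e1 <- synthetic_pair_ensemble(100, sigma_dd = 0.42, seed = 11)
  e2 <- synthetic_pair_ensemble(100, sigma_dd = 0.42, seed = 11)
  expect_identical(e1, e2)
  e0 <- synthetic_pair_ensemble(50, sigma_dd = 0, seed = 3)
  expect_true(all(e0$d_qha_ha == 0))
  big <- synthetic_pair_ensemble(1e4, sigma_dd = 0.42, seed = 5)
  se <- 0.42 / sqrt(2 * (1e4 - 1))
  expect_lt(abs(sd(big$d_qha_ha) - 0.42), 3 * se)
  expect_error(synthetic_pair_ensemble(0, seed = 1),
               class = "polyphonon_value_error")
  expect_error(synthetic_pair_ensemble(10), class = "polyphonon_value_error")
})

test_that("the two diatomic packings share one conformer", {
  a <- fx_dia("alpha"); b <- fx_dia("beta")
  ga <- polyphonon:::unwrap_unit(a$crystal, a$crystal$rigid_units[[1]])
  gb <- polyphonon:::unwrap_unit(b$crystal, b$crystal$rigid_units[[1]])
  # same rigid molecule in both packings (2 atoms: superpose directly)
  da <- sqrt(sum((ga[1, ] - ga[2, ])^2))
  db <- sqrt(sum((gb[1, ] - gb[2, ])^2))
  expect_equal(da, db, tolerance = 1e-5)
})
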