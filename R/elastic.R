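# Elastic tensor by central finite differences of the energy density with
# respect to the six Voigt strains, with optional re-relaxation of the
# rigid-body internal coordinates at every strained cell, and the
# Voigt/Reuss/Hill polycrystalline aggregate moduli.
#
# Voigt convention: strain vector e = (e1..e6) maps to the symmetric
# strain tensor with engineering shears, eps = [[e1, e6/2, e5/2],
# [e6/2, e2, e4/2], [e5/2, e4/2, e3]]; the factor-2 bookkeeping of the
# shear components is therefore carried by the tensor map, and C44 etc.
# come out directly in the standard convention.

.voigt_to_tensor <- function(e) {
  matrix(c(e[1], e[6] / 2, e[5] / 2,
           e[6] / 2, e[2], e[4] / 2,
           e[5] / 2, e[4] / 2, e[3]), 3, 3)
}

# homogeneously strain a crystal: cell vectors a' = (1 + eps) a, molecular
# centres of mass move affinely, rigid internal geometry is unchanged
.apply_strain <- function(crystal, eps) {
  Fdef <- diag(3) + eps
  geom <- .mol_geometry(crystal)
  cr <- crystal
  cr$lattice <- crystal$lattice %*% t(Fdef)
  Linv <- solve(cr$lattice)
  for (u in seq_len(n_molecules(crystal))) {
    idx <- crystal$rigid_units[[u]]
    m <- crystal$atoms$mass[idx]
    com <- colSums(geom$xyz[idx, , drop = FALSE] * m) / sum(m)
    rel <- sweep(geom$xyz[idx, , drop = FALSE], 2, com)
    newx <- sweep(rel, 2, drop(Fdef %*% com), "+")
    cr$atoms[idx, c("x", "y", "z")] <- (newx %*% Linv) %% 1
  }
  cr
}

#' Elastic stiffness tensor by finite strains
#'
#' Second derivatives of the energy density with respect to the six Voigt
#' strains by central differences, with the rigid-body internal coordinates
#' re-relaxed at every strained cell (relaxed-ion tensor) or frozen
#' (clamped-ion).
#'
#' @param crystal An optimized `crystal`.
#' @param ff A `forcefield`.
#' @param strain Strain step magnitude (default 0.002).
#' @param relax_internal Re-relax molecular positions/orientations in each
#'   strained cell (default TRUE). Internal relaxation can only soften the
#'   tensor.
#' @return Object of class `elastic_tensor`: `c` (6x6 symmetric, GPa),
#'   `relaxed_internal`, `volume`.
#' @export
elastic_tensor <- function(crystal, ff, strain = 0.002,
                           relax_internal = TRUE) {
  V0 <- cell_volume(crystal)
  M <- n_molecules(crystal)
  # internal dof exist only with >1 unit or any librational freedom
  has_internal <- M > 1 ||
    any(vapply(seq_len(M),
               function(u) length(crystal$rigid_units[[u]]) > 1, TRUE))
  Ecell <- function(e) {
    cr <- .apply_strain(crystal, .voigt_to_tensor(e))
    if (relax_internal && has_internal) {
      r <- tryCatch(
        optimize_crystal(cr, ff, fix_cell = TRUE, tol = 1e-5,
                         check_change = FALSE),
        polyphonon_error = function(err) stop_polyphonon(
          sprintf("internal relaxation failed at strain (%s): %s",
                  paste(signif(e, 3), collapse = ", "),
                  conditionMessage(err)),
          "polyphonon_instability_error"))
      r$enthalpy * M
    } else {
      lattice_energy(cr, ff)$e_inter * M
    }
  }
  d <- strain
  E0 <- Ecell(numeric(6))
  C <- matrix(0, 6, 6)
  ei <- function(i, s) { e <- numeric(6); e[i] <- s * d; e }
  for (a in 1:6) {
    C[a, a] <- (Ecell(ei(a, 1)) - 2 * E0 + Ecell(ei(a, -1))) / d^2
  }
  for (a in 1:5) for (b in (a + 1):6) {
    epp <- ei(a, 1); epp[b] <- d
    epm <- ei(a, 1); epm[b] <- -d
    emp <- ei(a, -1); emp[b] <- d
    emm <- ei(a, -1); emm[b] <- -d
    C[a, b] <- C[b, a] <-
      (Ecell(epp) - Ecell(epm) - Ecell(emp) + Ecell(emm)) / (4 * d^2)
  }
  Cgpa <- C / V0 * .const$kjmolA3_to_GPa
  Cgpa <- (Cgpa + t(Cgpa)) / 2
  structure(list(c = Cgpa, relaxed_internal = relax_internal && has_internal,
                 volume = V0),
            class = "elastic_tensor")
}

#' @export
print.elastic_tensor <- function(x, ...) {
  cat(sprintf("elastic tensor (GPa, %s-ion):\n",
              if (x$relaxed_internal) "relaxed" else "clamped"))
  print(round(x$c, 3))
  invisible(x)
}

#' Voigt, Reuss and Hill aggregate moduli
#'
#' Polycrystalline bulk (K) and shear (G) moduli: the Voigt (uniform
#' strain, upper) and Reuss (uniform stress, lower) bounds and their
#' arithmetic mean, the Hill average.
#'
#' @param c An `elastic_tensor` or a 6x6 symmetric matrix in GPa.
#' @return List of class `aggregate_moduli` with `k_voigt`, `k_reuss`,
#'   `k_hill`, `g_voigt`, `g_reuss`, `g_hill` (GPa) and `definite`.
#' @export
hill_moduli <- function(c) {
  C <- if (inherits(c, "elastic_tensor")) c$c else as.matrix(c)
  if (max(abs(C - t(C))) > 1e-6) stop_value("elastic tensor must be symmetric")
  kv <- (C[1, 1] + C[2, 2] + C[3, 3] +
           2 * (C[1, 2] + C[1, 3] + C[2, 3])) / 9
  gv <- (C[1, 1] + C[2, 2] + C[3, 3] - C[1, 2] - C[1, 3] - C[2, 3] +
           3 * (C[4, 4] + C[5, 5] + C[6, 6])) / 15
  S <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(S)) {
    stop_polyphonon("elastic tensor is singular; Reuss bound undefined",
                    "polyphonon_singular_error")
  }
  kr <- 1 / (S[1, 1] + S[2, 2] + S[3, 3] + 2 * (S[1, 2] + S[1, 3] + S[2, 3]))
  gr <- 15 / (4 * (S[1, 1] + S[2, 2] + S[3, 3]) -
                4 * (S[1, 2] + S[1, 3] + S[2, 3]) +
                3 * (S[4, 4] + S[5, 5] + S[6, 6]))
  definite <- all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!definite) {
    warning("elastic tensor is not positive definite; moduli reported for diagnostics only",
            call. = FALSE)
  }
  structure(list(k_voigt = kv, k_reuss = kr, k_hill = (kv + kr) / 2,
                 g_voigt = gv, g_reuss = gr, g_hill = (gv + gr) / 2,
                 definite = definite),
            class = "aggregate_moduli")
}

#' @export
print.aggregate_moduli <- function(x, ...) {
  cat(sprintf(
    "K (GPa): Reuss %.3f <= Hill %.3f <= Voigt %.3f\nG (GPa): Reuss %.3f <= Hill %.3f <= Voigt %.3f\n",
    x$k_reuss, x$k_hill, x$k_voigt, x$g_reuss, x$g_hill, x$g_voigt))
  invisible(x)
}

#' Temperature softening of the aggregate moduli
#'
#' Computes the elastic tensor and Hill moduli on each thermally expanded
#' quasi-harmonic structure and reports the percentage decrease relative to
#' the 0 K reference.
#'
#' @param reference The 0 K optimized `crystal`.
#' @param qha List of `qha_result` objects (or expanded crystals).
#' @param ff A `forcefield`.
#' @param strain Strain step for the tensors.
#' @param relax_internal Passed to [elastic_tensor()]; `FALSE` is exact for
#'   crystals whose atoms sit on centrosymmetric positions (e.g. fcc).
#' @return data.frame with per-temperature `T`, `k_hill`, `g_hill`,
#'   `k_decrease_pct`, `g_decrease_pct` and an `error` column for
#'   temperatures whose expanded structure failed.
#' @export
softening_profile <- function(reference, qha, ff, strain = 0.002,
                              relax_internal = TRUE) {
  m0 <- hill_moduli(elastic_tensor(reference, ff, strain, relax_internal))
  rows <- lapply(qha, function(st) {
    Tt <- if (inherits(st, "qha_result")) st$T else NA_real_
    cr <- if (inherits(st, "qha_result")) st$expanded else st
    res <- tryCatch({
      m <- hill_moduli(elastic_tensor(cr, ff, strain, relax_internal))
      data.frame(T = Tt, k_hill = m$k_hill, g_hill = m$g_hill,
                 k_decrease_pct = (m0$k_hill - m$k_hill) / m0$k_hill * 100,
                 g_decrease_pct = (m0$g_hill - m$g_hill) / m0$g_hill * 100,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, polyphonon_error = function(e) {
      data.frame(T = Tt, k_hill = NA_real_, g_hill = NA_real_,
                 k_decrease_pct = NA_real_, g_decrease_pct = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_moduli") <- m0
  out
}
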