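# Pairwise polymorph comparison: conformer RMSD filter (Kabsch
# superposition), stability re-ranking and enantiotropy/divergence
# classification, error statistics, and survey summaries over many pairs.

#' Minimum RMSD between two conformers after rigid superposition
#'
#' Optimal-rotation (Kabsch) superposition of two matched coordinate sets;
#' hydrogens can be excluded, matching the usual packing-polymorph filter
#' (conformers within 0.25 A are considered the same conformer).
#'
#' @param mol_a,mol_b n x 3 Cartesian coordinate matrices with matched
#'   atom order, or data.frames with columns `element`, `x`, `y`, `z`.
#' @param ignore_h Drop hydrogen atoms before superposing (requires
#'   element information).
#' @param elements Optional element vector when coordinates are plain
#'   matrices.
#' @return RMSD in Angstrom after optimal superposition.
#' @export
conformer_rmsd <- function(mol_a, mol_b, ignore_h = TRUE, elements = NULL) {
  getxyz <- function(m) {
    if (is.data.frame(m)) {
      list(xyz = as.matrix(m[, c("x", "y", "z")]), el = m$element)
    } else {
      list(xyz = as.matrix(m), el = elements)
    }
  }
  a <- getxyz(mol_a); b <- getxyz(mol_b)
  if (nrow(a$xyz) != nrow(b$xyz)) {
    stop_value("atom counts differ; a matched correspondence is required")
  }
  keep <- rep(TRUE, nrow(a$xyz))
  if (ignore_h) {
    if (is.null(a$el) || is.null(b$el)) {
      stop_value("ignore_h = TRUE requires element information")
    }
    keep <- a$el != "H" & b$el != "H"
  }
  X <- a$xyz[keep, , drop = FALSE]
  Y <- b$xyz[keep, , drop = FALSE]
  if (nrow(X) < 3) stop_value("need at least 3 (heavy) atoms")
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Y, X))          # Kabsch: rotate Y onto X
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((X - Y %*% R)^2)))
}

#' Classify a polymorph pair from its 0 K and melting-point differences
#'
#' A pair whose free-energy difference changes sign between 0 K and the
#' melting point is re-ranked by temperature: the model predicts an
#' enantiotropic relationship. Otherwise the pair is monotropic-predicted,
#' with its curves diverging (|dA| grows) or converging. Differences within
#' `tol` of zero are reported as degenerate, never silently assigned.
#'
#' @param d_a0 Free-energy difference (B - A) at 0 K (with ZPE), kJ mol^-1.
#' @param d_a_tm Free-energy difference at the melting point, kJ mol^-1.
#' @param tol Degeneracy tolerance, kJ mol^-1 (default 0.01).
#' @return List of class `pair_class`: `reranked`, `relationship`
#'   (`"enantiotropic-predicted"`, `"monotropic-predicted"` or
#'   `"degenerate"`), `curve_shape` (`"diverging"`, `"converging"` or
#'   `"degenerate"`).
#' @export
classify_pair <- function(d_a0, d_a_tm, tol = 0.01) {
  if (tol < 0) stop_value("tol must be non-negative")
  deg0 <- abs(d_a0) <= tol
  degT <- abs(d_a_tm) <= tol
  if (deg0 || degT) {
    out <- list(reranked = FALSE, relationship = "degenerate",
                curve_shape = "degenerate")
  } else if (sign(d_a0) != sign(d_a_tm)) {
    out <- list(reranked = TRUE, relationship = "enantiotropic-predicted",
                curve_shape = "crossing")
  } else {
    out <- list(reranked = FALSE, relationship = "monotropic-predicted",
                curve_shape = if (abs(d_a_tm) > abs(d_a0)) "diverging"
                              else "converging")
  }
  structure(out, class = "pair_class")
}

#' @export
print.pair_class <- function(x, ...) {
  cat(sprintf("pair: %s (%s)%s\n", x$relationship, x$curve_shape,
              if (x$reranked) ", re-ranked by temperature" else ""))
  invisible(x)
}

#' Error statistics for calculated vs experimental property pairs
#'
#' Mean absolute percentage error and mean signed percentage error,
#' the summary used for comparing calculated thermal-expansion
#' coefficients with experiment.
#'
#' @param pairs data.frame with columns `calc` and `exp` (or a 2-column
#'   matrix), experimental values non-zero.
#' @return List of class `error_stats`: `mape` (%), `mean_signed` (%),
#'   `n`.
#' @export
error_stats <- function(pairs) {
  p <- as.data.frame(pairs)
  if (!all(c("calc", "exp") %in% names(p))) {
    names(p)[1:2] <- c("calc", "exp")
  }
  if (nrow(p) < 1) stop_value("need at least one (calc, exp) pair")
  zero <- which(p$exp == 0)
  if (length(zero)) {
    stop_value(paste("zero experimental value in row(s):",
                     paste(zero, collapse = ", ")))
  }
  rel <- (p$calc - p$exp) / p$exp
  structure(list(mape = mean(abs(rel)) * 100,
                 mean_signed = mean(rel) * 100, n = nrow(p)),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("MA%%E = %.1f%%, mean signed error = %.1f%% (n = %d)\n",
              x$mape, x$mean_signed, x$n))
  invisible(x)
}

#' Survey a set of polymorph pairs
#'
#' Fractions of re-ranked and diverging pairs plus distribution summaries
#' of the lattice-energy, 0 K and melting-point free-energy differences
#' and the thermal-expansion (QHA minus HA) contribution.
#'
#' @param pairs data.frame with columns `d_elatt`, `d_a0`, `d_a_tm`
#'   (kJ mol^-1; optionally `d_qha_ha`), one row per polymorph pair.
#' @param tol Degeneracy tolerance for the classification.
#' @return List of class `pair_survey`: `n`, `frac_reranked`,
#'   `frac_diverging`, `frac_degenerate` and a `summary` data.frame
#'   (mean, sd, quartiles per column).
#' @export
survey <- function(pairs, tol = 0.01) {
  p <- as.data.frame(pairs)
  if (nrow(p) < 1) stop_value("need at least one pair")
  cls <- lapply(seq_len(nrow(p)),
                function(i) classify_pair(p$d_a0[i], p$d_a_tm[i], tol))
  rel <- vapply(cls, function(x) x$relationship, "")
  shp <- vapply(cls, function(x) x$curve_shape, "")
  cols <- intersect(c("d_elatt", "d_a0", "d_a_tm", "d_qha_ha"), names(p))
  sm <- do.call(rbind, lapply(cols, function(cc) {
    v <- p[[cc]]
    data.frame(quantity = cc, mean = mean(v), sd = stats::sd(v),
               q25 = unname(stats::quantile(v, .25)),
               median = stats::median(v),
               q75 = unname(stats::quantile(v, .75)),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    n = nrow(p),
    frac_reranked = mean(rel == "enantiotropic-predicted"),
    frac_diverging = mean(shp == "diverging"),
    frac_degenerate = mean(rel == "degenerate"),
    summary = sm),
    class = "pair_survey")
}

#' @export
print.pair_survey <- function(x, ...) {
  cat(sprintf(
    "%d pairs: %.0f%% re-ranked (enantiotropic-predicted), %.0f%% diverging, %.0f%% degenerate\n",
    x$n, 100 * x$frac_reranked, 100 * x$frac_diverging,
    100 * x$frac_degenerate))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Full quasi-harmonic comparison of one polymorph pair
#'
#' Runs the end-to-end pipeline for two crystals of the same compound:
#' optimize both at 0 K, compute QHA free energies at 0 K and at the
#' family melting temperature, and classify the pair.
#'
#' @param crystal_a,crystal_b The two polymorphs (starting structures).
#' @param ff A `forcefield`.
#' @param t_m Family melting temperature, K (one per polymorph family).
#' @param id_a,id_b Labels.
#' @param grid Phonon k-grid.
#' @param tol Degeneracy tolerance for classification, kJ mol^-1.
#' @param optimize Optimize the inputs first (default TRUE; set FALSE if
#'   already at their minima).
#' @return List of class `polymorph_pair` with `d_elatt`, `d_a0`,
#'   `d_a_tm` (B minus A, kJ mol^-1), `t_m`, the classification fields of
#'   [classify_pair()], and the per-polymorph `qha_0` / `qha_tm` states.
#' @export
compare_polymorphs <- function(crystal_a, crystal_b, ff, t_m,
                               id_a = "A", id_b = "B", grid = c(3, 3, 3),
                               tol = 0.01, optimize = TRUE) {
  prep <- function(cr) {
    if (optimize) optimize_crystal(cr, ff)$crystal else cr
  }
  a <- prep(crystal_a); b <- prep(crystal_b)
  qa0 <- qha_state(a, ff, 0, grid = grid)
  qb0 <- qha_state(b, ff, 0, grid = grid)
  qaT <- qha_state(a, ff, t_m, grid = grid)
  qbT <- qha_state(b, ff, t_m, grid = grid)
  d_a0 <- qb0$a_qha - qa0$a_qha
  d_a_tm <- qbT$a_qha - qaT$a_qha
  cls <- classify_pair(d_a0, d_a_tm, tol)
  structure(list(
    id_a = id_a, id_b = id_b,
    d_elatt = qb0$e_latt_T - qa0$e_latt_T,
    d_a0 = d_a0, d_a_tm = d_a_tm, t_m = t_m,
    reranked = cls$reranked, relationship = cls$relationship,
    curve_shape = cls$curve_shape,
    qha_0 = list(a = qa0, b = qb0), qha_tm = list(a = qaT, b = qbT)),
    class = "polymorph_pair")
}

#' @export
print.polymorph_pair <- function(x, ...) {
  cat(sprintf(
    "%s vs %s: dE_latt = %+.3f, dA(0) = %+.3f, dA(%.0f K) = %+.3f kJ/mol -> %s (%s)\n",
    x$id_b, x$id_a, x$d_elatt, x$d_a0, x$t_m, x$d_a_tm, x$relationship,
    x$curve_shape))
  invisible(x)
}
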