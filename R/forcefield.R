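# Force-field container and plain-text file format.
#
# File format (whitespace separated, '#' comments):
#   [types]
#   label element mass charge
#   [pairs]
#   type1 type2 A B C          # exp-6: A exp(-B R) - C R^-6
#   [springs]
#   type1 type2 kappa r0 rcut  # harmonic test potential 0.5 k (R - r0)^2
#   [settings]
#   com_cutoff 20
#   epsilon_r 5.0
#   ewald_accuracy 1e-10

#' Construct a ForceField object
#'
#' @param types data.frame(label, element, mass, charge): the atom types.
#' @param pairs data.frame(t1, t2, A, B, C): exp-6 parameters
#'   (kJ mol^-1, A^-1, kJ mol^-1 A^6) keyed by unordered type pair.
#' @param springs Optional data.frame(t1, t2, kappa, r0, rcut): harmonic
#'   pair potentials `0.5*kappa*(R - r0)^2` applied below `rcut`, used by
#'   the analytic test lattices.
#' @param com_cutoff Whole-molecule centre-of-mass cutoff for the short
#'   range (exp-6 and spring) interactions, Angstrom. Default 20.
#' @param taper Width (Angstrom) of the smooth quintic switch applied to
#'   each molecule pair's short-range energy just inside `com_cutoff`, so
#'   the energy surface is C2-continuous when pairs cross the cutoff;
#'   0 gives the sharp cutoff. Default 1.
#' @param ewald_accuracy Target relative truncation accuracy of the Ewald
#'   sums (dimensionless).
#' @param epsilon_r Relative permittivity metadata carried with the model
#'   (used when charges were derived in a polarizable continuum); never
#'   applied as an energy scale.
#' @param combine Allow geometric-mean (A, C) / arithmetic-mean (B)
#'   combination rules for missing cross pairs; each use emits a warning.
#' @return Object of class `forcefield`.
#' @export
forcefield <- function(types, pairs = NULL, springs = NULL,
                       com_cutoff = 20, taper = 1, ewald_accuracy = 1e-10,
                       epsilon_r = 5.0, combine = TRUE) {
  types <- as.data.frame(types, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "element", "mass", "charge") %in% names(types)))
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    stopifnot(all(c("t1", "t2", "A", "B", "C") %in% names(pairs)))
    if (any(pairs$B <= 0)) stop_value("exp-6 B parameters must be positive")
    if (any(pairs$A < 0) || any(pairs$C < 0)) {
      stop_value("exp-6 A and C parameters must be non-negative")
    }
  }
  if (!is.null(springs)) {
    springs <- as.data.frame(springs, stringsAsFactors = FALSE)
    stopifnot(all(c("t1", "t2", "kappa", "r0", "rcut") %in% names(springs)))
  }
  if (taper < 0 || taper >= com_cutoff) {
    stop_value("taper width must be in [0, com_cutoff)")
  }
  structure(list(types = types, pairs = pairs, springs = springs,
                 com_cutoff = com_cutoff, taper = taper,
                 ewald_accuracy = ewald_accuracy,
                 epsilon_r = epsilon_r, combine = combine),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf(
    "forcefield: %d types, %d exp-6 pairs, %d springs, COM cutoff %.1f A\n",
    nrow(x$types), if (is.null(x$pairs)) 0L else nrow(x$pairs),
    if (is.null(x$springs)) 0L else nrow(x$springs), x$com_cutoff))
  invisible(x)
}

# Look up exp-6 parameters for every row of a (type_i, type_k) pair list.
# Returns matrix with columns A, B, C (zero row = no exp-6 term).
ff_pair_params <- function(ff, ti, tk) {
  n <- length(ti)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  if (is.null(ff$pairs) || n == 0) return(out)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tab <- ff$pairs
  kmap <- key(tab$t1, tab$t2)
  idx <- match(key(ti, tk), kmap)
  hit <- !is.na(idx)
  out[hit, ] <- as.matrix(tab[idx[hit], c("A", "B", "C")])
  if (any(!hit)) {
    # combination-rule fallback from like pairs, if available
    like <- match(key(ti, ti), kmap)
    likek <- match(key(tk, tk), kmap)
    fb <- !hit & !is.na(like) & !is.na(likek)
    if (any(fb)) {
      if (!isTRUE(ff$combine)) {
        stop_value("missing cross-pair parameters and combination rules disabled")
      }
      warning(sprintf(
        "combining rules used for %d missing cross pair(s): %s",
        sum(fb),
        paste(unique(key(ti, tk)[fb]), collapse = "; ")), call. = FALSE)
      out[fb, "A"] <- sqrt(tab$A[like[fb]] * tab$A[likek[fb]])
      out[fb, "C"] <- sqrt(tab$C[like[fb]] * tab$C[likek[fb]])
      out[fb, "B"] <- (tab$B[like[fb]] + tab$B[likek[fb]]) / 2
    }
    miss <- !hit & !fb
    if (any(miss)) {
      stop_value(paste("no exp-6 parameters for pair(s):",
                       paste(unique(key(ti, tk)[miss]), collapse = "; ")))
    }
  }
  out
}

# Spring parameters (kappa, r0, rcut); zero kappa = no spring.
ff_spring_params <- function(ff, ti, tk) {
  n <- length(ti)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("kappa", "r0", "rcut")))
  if (is.null(ff$springs) || n == 0) return(out)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  idx <- match(key(ti, tk), key(ff$springs$t1, ff$springs$t2))
  hit <- !is.na(idx)
  out[hit, ] <- as.matrix(ff$springs[idx[hit], c("kappa", "r0", "rcut")])
  out
}

# Fill atom charges / masses from the force field's [types] table where the
# crystal does not carry them.
apply_ff_types <- function(crystal, ff) {
  idx <- match(crystal$atoms$ff_type, ff$types$label)
  if (anyNA(idx)) {
    stop_value(paste("ff_type(s) not in force field:",
                     paste(unique(crystal$atoms$ff_type[is.na(idx)]),
                           collapse = ", ")))
  }
  crystal$atoms$charge <- ff$types$charge[idx]
  crystal$atoms$mass <- ff$types$mass[idx]
  crystal
}

#' Read a force field from its plain-text file format
#'
#' @param path File path. See the package README for the format.
#' @return A `forcefield` object.
#' @export
read_forcefield <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  types <- list(); pairs <- list(); springs <- list()
  settings <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) { section <- gsub("\\[|\\]", "", ln); next }
    tk <- strsplit(ln, "\\s+")[[1]]
    if (section == "types") {
      types[[length(types) + 1L]] <- data.frame(
        label = tk[1], element = tk[2], mass = as.numeric(tk[3]),
        charge = as.numeric(tk[4]), stringsAsFactors = FALSE)
    } else if (section == "pairs") {
      pairs[[length(pairs) + 1L]] <- data.frame(
        t1 = tk[1], t2 = tk[2], A = as.numeric(tk[3]), B = as.numeric(tk[4]),
        C = as.numeric(tk[5]), stringsAsFactors = FALSE)
    } else if (section == "springs") {
      springs[[length(springs) + 1L]] <- data.frame(
        t1 = tk[1], t2 = tk[2], kappa = as.numeric(tk[3]),
        r0 = as.numeric(tk[4]), rcut = as.numeric(tk[5]),
        stringsAsFactors = FALSE)
    } else if (section == "settings") {
      settings[[tk[1]]] <- as.numeric(tk[2])
    }
  }
  if (!length(types)) stop_format("force field file has no [types] section")
  forcefield(
    do.call(rbind, types),
    pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
    springs = if (length(springs)) do.call(rbind, springs) else NULL,
    com_cutoff = settings$com_cutoff %||% 20,
    taper = settings$taper %||% 1,
    ewald_accuracy = settings$ewald_accuracy %||% 1e-10,
    epsilon_r = settings$epsilon_r %||% 5.0)
}

#' Write a force field to its plain-text file format
#'
#' @param ff A `forcefield` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_forcefield <- function(ff, path) {
  ln <- c("# polyphonon force field",
          "[types]",
          sprintf("%s %s %.6f %.6f", ff$types$label, ff$types$element,
                  ff$types$mass, ff$types$charge))
  if (!is.null(ff$pairs)) {
    ln <- c(ln, "[pairs]",
            sprintf("%s %s %.8g %.8g %.8g", ff$pairs$t1, ff$pairs$t2,
                    ff$pairs$A, ff$pairs$B, ff$pairs$C))
  }
  if (!is.null(ff$springs)) {
    ln <- c(ln, "[springs]",
            sprintf("%s %s %.8g %.8g %.8g", ff$springs$t1, ff$springs$t2,
                    ff$springs$kappa, ff$springs$r0, ff$springs$rcut))
  }
  ln <- c(ln, "[settings]",
          sprintf("com_cutoff %.6g", ff$com_cutoff),
          sprintf("taper %.6g", ff$taper %||% 1),
          sprintf("ewald_accuracy %.6g", ff$ewald_accuracy),
          sprintf("epsilon_r %.6g", ff$epsilon_r))
  writeLines(ln, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
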