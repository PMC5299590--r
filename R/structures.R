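# Crystal data model and CIF input/output.
#
# A crystal is stored as an S3 list:
#   lattice     3x3 matrix, Angstrom; ROWS are the cell vectors a, b, c
#   atoms       data.frame(element, mass, x, y, z, charge, ff_type)
#               with x, y, z fractional coordinates wrapped into [0, 1)
#   rigid_units list of integer vectors partitioning the atom indices
#               into rigid molecules

#' Construct a Crystal object
#'
#' @param lattice 3x3 numeric matrix whose rows are the cell vectors
#'   (Angstrom). Must be right-handed (positive scalar triple product).
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`
#'   (fractional) and optionally `mass` (amu, defaults to the standard
#'   atomic weight), `charge` (e, defaults to 0) and `ff_type`
#'   (defaults to the element symbol).
#' @param rigid_units list of integer vectors partitioning `1:nrow(atoms)`
#'   into rigid molecules, or `NULL` to treat every atom as its own unit.
#' @return Object of class `crystal`.
#' @export
crystal <- function(lattice, atoms, rigid_units = NULL) {
  lattice <- matrix(as.numeric(lattice), 3, 3)
  if (det(lattice) <= 0) {
    stop_value("lattice must be right-handed with positive volume")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop_value("crystal must contain at least one atom")
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop_format("atoms needs columns: element, x, y, z")
  }
  if (is.null(atoms$mass)) atoms$mass <- atomic_mass(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$ff_type)) atoms$ff_type <- atoms$element
  if (any(atoms$mass <= 0)) stop_value("atom masses must be positive")
  for (cc in c("x", "y", "z")) atoms[[cc]] <- atoms[[cc]] %% 1
  if (is.null(rigid_units)) rigid_units <- as.list(seq_len(nrow(atoms)))
  rigid_units <- lapply(rigid_units, as.integer)
  idx <- sort(unlist(rigid_units))
  if (!identical(idx, seq_len(nrow(atoms)))) {
    stop_value("rigid_units must partition the atom indices exactly")
  }
  structure(list(lattice = lattice, atoms = atoms,
                 rigid_units = rigid_units),
            class = "crystal")
}

#' @export
print.crystal <- function(x, ...) {
  cat(sprintf("crystal: %d atoms, %d rigid unit(s), V = %.4f A^3\n",
              nrow(x$atoms), length(x$rigid_units), cell_volume(x)))
  invisible(x)
}

#' Unit-cell volume
#'
#' @param crystal A `crystal` object.
#' @return Volume in Angstrom^3 (scalar triple product of the cell vectors).
#' @export
cell_volume <- function(crystal) det(crystal$lattice)

#' Number of rigid molecules in the cell
#'
#' @param crystal A `crystal` object.
#' @return Integer Z of the P1 cell.
#' @export
n_molecules <- function(crystal) length(crystal$rigid_units)

#' Cartesian coordinates of all atoms
#'
#' @param crystal A `crystal` object.
#' @return n x 3 matrix of Cartesian positions in Angstrom.
#' @export
cart_coords <- function(crystal) {
  as.matrix(crystal$atoms[, c("x", "y", "z")]) %*% crystal$lattice
}

# Cell parameters (a, b, c, alpha, beta, gamma) from a lattice matrix.
lattice_to_cellpar <- function(lattice) {
  lens <- sqrt(rowSums(lattice^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  c(a = lens[1], b = lens[2], c = lens[3],
    alpha = ang(lattice[2, ], lattice[3, ]),
    beta  = ang(lattice[1, ], lattice[3, ]),
    gamma = ang(lattice[1, ], lattice[2, ]))
}

# Standard construction: a along x, b in the xy plane.
cellpar_to_lattice <- function(a, b, c, alpha, beta, gamma) {
  al <- alpha * pi / 180; be <- beta * pi / 180; ga <- gamma * pi / 180
  bx <- b * cos(ga); by <- b * sin(ga)
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop_value("inconsistent cell parameters")
  rbind(c(a, 0, 0), c(bx, by, 0), c(cx, cy, sqrt(cz2)))
}

# Unwrap the atoms of one rigid unit into a contiguous molecule: every atom
# is moved to the periodic image closest to the unit's first atom (greedy
# minimum-image walk, adequate for molecules smaller than half a cell).
# Returns Cartesian coordinates (m x 3).
unwrap_unit <- function(crystal, unit) {
  fr <- as.matrix(crystal$atoms[unit, c("x", "y", "z"), drop = FALSE])
  ref <- fr[1, ]
  d <- sweep(fr, 2, ref)
  d <- d - round(d)
  sweep(d, 2, ref, "+") %*% crystal$lattice
}

#' Geometric description of one rigid unit
#'
#' Centre of mass, inertia tensor about the centre of mass and an
#' orientation quaternion (identity at construction; the optimizer composes
#' rotation increments onto it).
#'
#' @param crystal A `crystal` object.
#' @param i Index of the rigid unit.
#' @return List with `atom_indices`, `com` (Angstrom), `inertia_tensor`
#'   (amu A^2), `orientation` (unit quaternion, w first) and `mass` (amu).
#' @export
rigid_unit_info <- function(crystal, i) {
  unit <- crystal$rigid_units[[i]]
  xyz <- unwrap_unit(crystal, unit)
  m <- crystal$atoms$mass[unit]
  com <- colSums(xyz * m) / sum(m)
  rel <- sweep(xyz, 2, com)
  inert <- matrix(0, 3, 3)
  for (j in seq_along(unit)) {
    r <- rel[j, ]
    inert <- inert + m[j] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  list(atom_indices = unit, com = com, inertia_tensor = inert,
       orientation = c(1, 0, 0, 0), mass = sum(m))
}

# CIF I/O ----------------------------------------------------------------

# Tokenize one CIF line, respecting single/double quotes.
.cif_tokens <- function(line) {
  line <- sub("#.*$", "", line)
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character())
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

# Parse "x, y, z"-style symmetry operator into a (3x3 matrix, shift) pair.
.parse_symop <- function(op) {
  parts <- strsplit(tolower(gsub("\\s", "", op)), ",")[[1]]
  if (length(parts) != 3) stop_format(paste("bad symmetry operator:", op))
  rot <- matrix(0, 3, 3); shift <- numeric(3)
  for (r in 1:3) {
    expr <- parts[r]
    # split into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "\\+")[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sgn <- 1
      if (startsWith(tm, "-")) { sgn <- -1; tm <- substring(tm, 2) }
      if (grepl("[xyz]$", tm)) {
        axis <- match(substring(tm, nchar(tm)), c("x", "y", "z"))
        coef <- sub("[xyz]$", "", tm)
        coef <- sub("\\*$", "", coef)
        val <- if (nzchar(coef)) .parse_frac(coef) else 1
        rot[r, axis] <- rot[r, axis] + sgn * val
      } else {
        shift[r] <- shift[r] + sgn * .parse_frac(tm)
      }
    }
  }
  list(rot = rot, shift = shift)
}

.parse_frac <- function(s) {
  if (grepl("/", s)) {
    ab <- as.numeric(strsplit(s, "/")[[1]])
    ab[1] / ab[2]
  } else as.numeric(s)
}

# strip standard-uncertainty suffixes like 1.234(5)
.cif_num <- function(s) as.numeric(sub("\\(.*\\)$", "", s))

#' Read a crystal structure from a CIF file
#'
#' Supports the core CIF 1.1 subset this package writes: one data block with
#' `_cell_length_*` / `_cell_angle_*` items, an `_atom_site_*` loop with
#' `_atom_site_type_symbol` and fractional coordinates, and (optionally) a
#' symmetry-operator loop which is applied to expand the structure to P1.
#' Custom tags `_atom_site_charge` and `_atom_site_ff_type` carry point
#' charges and force-field atom types; when absent they can be filled from
#' a force field's `[types]` table later.
#'
#' @param path Path to the CIF file.
#' @param bond_scale If not `NULL`, rigid units are identified with
#'   [identify_rigid_units()] using this bond scale; `NULL` leaves every
#'   atom as its own unit.
#' @return A `crystal` object in P1 with fractional coordinates in [0, 1).
#' @export
read_cif <- function(path, bond_scale = 1.2) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  items <- list(); loops <- list()
  i <- 1; n <- length(lines)
  while (i <= n) {
    toks <- .cif_tokens(lines[i])
    if (length(toks) == 0) { i <- i + 1; next }
    if (tolower(toks[1]) == "loop_") {
      i <- i + 1
      tags <- character()
      while (i <= n) {
        tk <- .cif_tokens(lines[i])
        if (length(tk) == 1 && startsWith(tk[1], "_")) {
          tags <- c(tags, tolower(tk[1])); i <- i + 1
        } else break
      }
      rows <- list(); buf <- character()
      while (i <= n) {
        tk <- .cif_tokens(lines[i])
        if (length(tk) == 0) { i <- i + 1; break }
        if (startsWith(tk[1], "_") || tolower(tk[1]) == "loop_" ||
            startsWith(tolower(tk[1]), "data_")) break
        buf <- c(buf, tk)
        while (length(buf) >= length(tags)) {
          rows[[length(rows) + 1L]] <- buf[seq_along(tags)]
          buf <- buf[-seq_along(tags)]
        }
        i <- i + 1
      }
      if (length(rows)) {
        tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(tab) <- tags
        loops[[length(loops) + 1L]] <- tab
      }
    } else if (startsWith(toks[1], "_")) {
      if (length(toks) >= 2) items[[tolower(toks[1])]] <- toks[2]
      i <- i + 1
    } else i <- i + 1
  }

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  if (!all(need %in% names(items))) {
    stop_format("CIF is missing cell parameters (_cell_length_a/b/c)")
  }
  getn <- function(tag, default = NA_real_) {
    if (tag %in% names(items)) .cif_num(items[[tag]]) else default
  }
  lat <- cellpar_to_lattice(
    getn("_cell_length_a"), getn("_cell_length_b"), getn("_cell_length_c"),
    getn("_cell_angle_alpha", 90), getn("_cell_angle_beta", 90),
    getn("_cell_angle_gamma", 90))

  site <- NULL; symops <- list(list(rot = diag(3), shift = numeric(3)))
  for (tab in loops) {
    if (any(grepl("^_atom_site_fract", names(tab)))) site <- tab
    symtag <- intersect(c("_symmetry_equiv_pos_as_xyz",
                          "_space_group_symop_operation_xyz"), names(tab))
    if (length(symtag)) symops <- lapply(tab[[symtag[1]]], .parse_symop)
  }
  if (is.null(site)) stop_format("CIF has no _atom_site_ loop")
  colof <- function(tag) if (tag %in% names(site)) site[[tag]] else NULL
  elem <- colof("_atom_site_type_symbol")
  if (is.null(elem)) stop_format("CIF loop lacks _atom_site_type_symbol")
  if (!all(elem %in% names(.atomic_masses))) {
    stop_format(paste("unknown element symbol(s):",
                      paste(setdiff(elem, names(.atomic_masses)),
                            collapse = ", ")))
  }
  fr <- cbind(.cif_num(colof("_atom_site_fract_x")),
              .cif_num(colof("_atom_site_fract_y")),
              .cif_num(colof("_atom_site_fract_z")))
  chg <- colof("_atom_site_charge")
  chg <- if (is.null(chg)) rep(0, nrow(fr)) else .cif_num(chg)
  fft <- colof("_atom_site_ff_type")
  if (is.null(fft)) fft <- elem

  # expand symmetry to P1, deduplicating coincident sites
  allpos <- NULL; allel <- character(); allch <- numeric(); allty <- character()
  for (op in symops) {
    p <- t(op$rot %*% t(fr)) + matrix(op$shift, nrow(fr), 3, byrow = TRUE)
    p <- p %% 1
    allpos <- rbind(allpos, p)
    allel <- c(allel, elem); allch <- c(allch, chg); allty <- c(allty, fft)
  }
  keep <- rep(TRUE, nrow(allpos))
  for (j in seq_len(nrow(allpos))) {
    if (!keep[j]) next
    if (j < nrow(allpos)) {
      d <- sweep(allpos[(j + 1):nrow(allpos), , drop = FALSE], 2, allpos[j, ])
      d <- d - round(d)
      dup <- which(rowSums((d %*% lat)^2) < 1e-6)
      keep[j + dup] <- FALSE
    }
  }
  atoms <- data.frame(element = allel[keep],
                      x = allpos[keep, 1], y = allpos[keep, 2],
                      z = allpos[keep, 3],
                      charge = allch[keep], ff_type = allty[keep],
                      stringsAsFactors = FALSE)
  cr <- crystal(lat, atoms)
  if (!is.null(bond_scale)) {
    cr$rigid_units <- identify_rigid_units(cr, bond_scale)
  }
  cr
}

#' Write a crystal structure to a CIF file
#'
#' Writes a P1 core-CIF with cell parameters and fractional coordinates to
#' six decimals, plus the custom `_atom_site_charge` / `_atom_site_ff_type`
#' tags so that a read/write round trip preserves the full atom record.
#'
#' @param crystal A `crystal` object.
#' @param path Output path.
#' @param data_name Name of the CIF data block.
#' @return Invisibly, `path`.
#' @export
write_cif <- function(crystal, path, data_name = "polyphonon") {
  if (!inherits(crystal, "crystal") || nrow(crystal$atoms) == 0L) {
    stop_value("write_cif needs a crystal with at least one atom")
  }
  cp <- lattice_to_cellpar(crystal$lattice)
  at <- crystal$atoms
  lines <- c(
    sprintf("data_%s", data_name),
    "_symmetry_space_group_name_H-M   'P 1'",
    "_symmetry_Int_Tables_number      1",
    sprintf("_cell_length_a    %.6f", cp["a"]),
    sprintf("_cell_length_b    %.6f", cp["b"]),
    sprintf("_cell_length_c    %.6f", cp["c"]),
    sprintf("_cell_angle_alpha %.6f", cp["alpha"]),
    sprintf("_cell_angle_beta  %.6f", cp["beta"]),
    sprintf("_cell_angle_gamma %.6f", cp["gamma"]),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "  'x, y, z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_charge",
    "_atom_site_ff_type",
    sprintf("%s%d %s %.6f %.6f %.6f %.6f %s",
            at$element, seq_len(nrow(at)), at$element,
            at$x %% 1, at$y %% 1, at$z %% 1, at$charge, at$ff_type))
  tryCatch(writeLines(lines, path),
           error = function(e) stop_polyphonon(
             paste("cannot write CIF:", conditionMessage(e)),
             "polyphonon_io_error"))
  invisible(path)
}

#' Build a supercell
#'
#' Replicates the cell `n1 x n2 x n3` times. The rigid-unit partition is
#' replicated with the atoms, so lattice energies per molecule are
#' unchanged (extensivity).
#'
#' @param crystal A `crystal` object.
#' @param n1,n2,n3 Positive integer replication factors along a, b, c.
#' @return A `crystal` with `n1*n2*n3` times the atoms and volume.
#' @export
make_supercell <- function(crystal, n1, n2, n3) {
  n <- c(n1, n2, n3)
  if (any(n < 1) || any(n != round(n))) {
    stop_value("supercell factors must be positive integers")
  }
  if (all(n == 1)) return(crystal)
  at <- crystal$atoms
  na <- nrow(at)
  # make each molecule contiguous (unwrap across the cell boundary) before
  # replication, otherwise the copies would pair atoms from different
  # periodic images into one rigid unit
  fr <- as.matrix(at[, c("x", "y", "z")])
  for (u in crystal$rigid_units) {
    ref <- fr[u[1], ]
    d <- sweep(fr[u, , drop = FALSE], 2, ref)
    d <- d - round(d)
    fr[u, ] <- sweep(d, 2, ref, "+")
  }
  at$x <- fr[, 1]; at$y <- fr[, 2]; at$z <- fr[, 3]
  shifts <- as.matrix(expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1),
                                  k = 0:(n[3] - 1)))
  newat <- at[rep(seq_len(na), nrow(shifts)), , drop = FALSE]
  rep_sh <- shifts[rep(seq_len(nrow(shifts)), each = na), , drop = FALSE]
  newat$x <- (newat$x + rep_sh[, 1]) / n[1]
  newat$y <- (newat$y + rep_sh[, 2]) / n[2]
  newat$z <- (newat$z + rep_sh[, 3]) / n[3]
  rownames(newat) <- NULL
  units <- list()
  for (s in seq_len(nrow(shifts))) {
    off <- (s - 1L) * na
    units <- c(units, lapply(crystal$rigid_units, function(u) u + off))
  }
  crystal(diag(n) %*% crystal$lattice, newat, units)
}

#' Identify rigid molecular units from the bond graph
#'
#' Atoms closer than `bond_scale` times the sum of their covalent radii
#' (over all periodic images) are bonded; connected components of the bond
#' graph are the rigid units. A component that bonds to its own periodic
#' image (a polymer or framework) is rejected, because the rigid-body model
#' does not apply to it.
#'
#' @param crystal A `crystal` object.
#' @param bond_scale Multiplier on the covalent-radius sum (default 1.2).
#' @return List of integer vectors (the partition), ordered by first atom.
#' @export
identify_rigid_units <- function(crystal, bond_scale = 1.2) {
  at <- crystal$atoms
  na <- nrow(at)
  if (bond_scale <= 0) return(as.list(seq_len(na)))
  rad <- covalent_radius(at$element)
  fr <- as.matrix(at[, c("x", "y", "z")])
  # neighbour images -1..1 suffice for bonds if the cell is larger than two
  # bond lengths; include +-1 shells always.
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  bonds <- list()
  for (i in seq_len(na)) {
    for (j in i:na) {
      dj <- sweep(matrix(fr[j, ], nrow(sh), 3, byrow = TRUE) + sh, 2, fr[i, ])
      dcart <- dj %*% crystal$lattice
      dd <- sqrt(rowSums(dcart^2))
      cut <- bond_scale * (rad[i] + rad[j])
      hit <- which(dd < cut & dd > 1e-6)
      for (h in hit) bonds[[length(bonds) + 1L]] <- c(i, j, sh[h, ])
    }
  }
  # BFS with image-shift tracking: reaching an atom twice with different
  # lattice shifts means the component is infinite (polymer).
  shift <- matrix(0, na, 3)
  adj <- vector("list", na)
  for (b in bonds) {
    i <- b[1]; j <- b[2]; s <- b[3:5]
    adj[[i]] <- c(adj[[i]], list(c(j, s)))
    adj[[j]] <- c(adj[[j]], list(c(i, -s)))
  }
  comp <- rep(NA_integer_, na)
  ncomp <- 0L
  for (start in seq_len(na)) {
    if (!is.na(comp[start])) next
    ncomp <- ncomp + 1L
    comp[start] <- ncomp; shift[start, ] <- 0
    queue <- list(start)
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (e in adj[[i]]) {
        j <- e[1]; s <- e[2:4]
        newshift <- shift[i, ] + s
        if (is.na(comp[j])) {
          comp[j] <- ncomp; shift[j, ] <- newshift
          queue <- c(queue, list(j))
        } else if (any(abs(shift[j, ] - newshift) > 1e-9)) {
          stop_polyphonon(
            "bond graph spans the lattice (polymer/framework); rigid-body model inapplicable",
            "polyphonon_polymer_error")
        }
      }
    }
  }
  units <- split(seq_len(na), comp)
  units <- lapply(units, as.integer)
  names(units) <- NULL
  units[order(vapply(units, min, 1L))]
}
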