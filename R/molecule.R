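#' Bondi van der Waals radii (Angstrom)
#'
#' Element-keyed lookup used as the default atomic radius set for all surface
#' and volume computations. Values from the Bondi compilation; elements not
#' listed fall back to 1.70 A.
#'
#' @format named numeric vector, names are element symbols.
#' @export
bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
  Na = 2.27, K = 2.75, Cu = 1.40, Zn = 1.39
)

vdw_radius <- function(element) {
  r <- unname(bondi_radii[element])
  r[is.na(r)] <- 1.70
  r
}

#' Construct a molecule
#'
#' The package-wide substrate/ligand representation: a tibble of atoms plus a
#' bond list. Radii default to the Bondi set ([bondi_radii]); partial charges
#' and aromatic flags are optional and only required by the descriptors that
#' use them ([esp_extrema()], [surface_partition()]).
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `radius` (Angstrom), `charge` (e), `aromatic` (logical),
#'   `name` (atom label).
#' @param bonds optional data frame with columns `i`, `j` (1-based atom
#'   indices) and optionally `order`.
#' @param formal_charge molecular formal charge (e).
#' @param name molecule identifier.
#' @param meta named list of free-form metadata (e.g. analytic reference
#'   values attached by [gen_toy_molecule()]).
#' @return an object of class `molecule`.
#' @examples
#' m <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
#' compute_sasa(m)
#' @export
molecule <- function(atoms, bonds = NULL, formal_charge = 0, name = "mol",
                     meta = list()) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0) stop("molecule must contain at least one atom", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  if (!"radius" %in% names(atoms)) atoms$radius <- vdw_radius(atoms$element)
  if (any(atoms$radius <= 0)) stop("atomic radii must be positive", call. = FALSE)
  if (!"aromatic" %in% names(atoms)) atoms$aromatic <- FALSE
  if (!"name" %in% names(atoms)) {
    atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  has_charges <- "charge" %in% names(atoms) && !all(is.na(atoms$charge))
  if (has_charges) {
    if (abs(sum(atoms$charge) - formal_charge) > 0.01) {
      stop("sum of partial charges differs from formal charge by > 0.01 e",
           call. = FALSE)
    }
  } else {
    atoms$charge <- NA_real_
  }
  if (!is.null(bonds)) {
    bonds <- tibble::as_tibble(bonds)
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    if (nrow(bonds) > 0 &&
        (max(bonds$i, bonds$j) > nrow(atoms) || min(bonds$i, bonds$j) < 1)) {
      stop("bond indices out of range", call. = FALSE)
    }
  } else {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  }
  structure(
    list(atoms = atoms, bonds = bonds, formal_charge = formal_charge,
         name = name, meta = meta),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$name, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, formal charge ", x$formal_charge, "\n", sep = "")
  print(x$atoms, n = 5)
  invisible(x)
}

mol_xyz <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

n_atoms <- function(mol) nrow(mol$atoms)

# indices of atoms bonded to atom k
bonded_to <- function(mol, k) {
  b <- mol$bonds
  c(b$j[b$i == k], b$i[b$j == k])
}

# for each atom, the indices of attached hydrogens
attached_hydrogens <- function(mol) {
  lapply(seq_len(n_atoms(mol)), function(k) {
    nb <- bonded_to(mol, k)
    nb[mol$atoms$element[nb] == "H"]
  })
}

# TRUE for bonds whose removal leaves the endpoints connected (ring bonds)
ring_bond_flags <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(logical(0))
  vapply(seq_len(nrow(b)), function(k) {
    connected_without <- function() {
      adj <- b[-k, , drop = FALSE]
      seen <- rep(FALSE, n_atoms(mol))
      stack <- b$i[k]; seen[stack] <- TRUE
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        nb <- c(adj$j[adj$i == v], adj$i[adj$j == v])
        nb <- nb[!seen[nb]]
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
      seen[b$j[k]]
    }
    connected_without()
  }, logical(1))
}

#' Apply a rigid transform to a molecule
#'
#' Rotates then translates every atom; all descriptor and geometry code in the
#' package is invariant under this operation (up to quadrature noise), which
#' the test-suite exercises.
#'
#' @param mol a [molecule].
#' @param transform list with elements `R` (3x3) and `t` (length 3), e.g. from
#'   [random_rigid_transform()].
#' @return the transformed molecule.
#' @export
transform_molecule <- function(mol, transform) {
  xyz <- apply_rigid(mol_xyz(mol), transform)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Read a molecule from an SDF (V2000) file
#'
#' Reads the first record of an MDL V2000 file: counts line, atom block
#' (coordinates + element), bond block. Aromatic flags are set for bond type 4
#' and partial charges, if present, are taken from an `> <atom.charges>` data
#' field (one value per atom, whitespace-separated) as written by
#' [write_sdf()].
#'
#' @param path file path.
#' @return a [molecule].
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("not a valid SDF file: ", path, call. = FALSE)
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop("unparseable SDF counts line", call. = FALSE)
  atom_lines <- lines[5:(4 + na)]
  atoms <- tibble::tibble(
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)),
    element = trimws(substr(atom_lines, 31, 34))
  )
  bonds <- NULL
  aromatic <- rep(FALSE, na)
  if (nb > 0) {
    bond_lines <- lines[(5 + na):(4 + na + nb)]
    bi <- as.integer(substr(bond_lines, 1, 3))
    bj <- as.integer(substr(bond_lines, 4, 6))
    bo <- as.integer(substr(bond_lines, 7, 9))
    aromatic[unique(c(bi[bo == 4], bj[bo == 4]))] <- TRUE
    bonds <- tibble::tibble(i = bi, j = bj, order = bo)
  }
  atoms$aromatic <- aromatic
  chg_at <- grep("^> *<atom.charges>", lines)
  formal <- 0
  if (length(chg_at) == 1) {
    q <- as.numeric(strsplit(trimws(lines[chg_at + 1]), "\\s+")[[1]])
    if (length(q) == na) {
      atoms$charge <- q
      formal <- round(sum(q))
    }
  }
  molecule(atoms, bonds, formal_charge = formal,
           name = trimws(lines[1]))
}

#' Write a molecule to an SDF (V2000) file
#'
#' Bond type 4 is used for bonds between two aromatic atoms; partial charges
#' (when present) are stored in an `> <atom.charges>` data field so that
#' [read_sdf()] round-trips them.
#'
#' @param mol a [molecule].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mol, path) {
  a <- mol$atoms; b <- mol$bonds
  head <- c(mol$name, "  lacqsar", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b))
  atom_block <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, a$element)
  bond_block <- character(0)
  if (nrow(b) > 0) {
    ord <- ifelse(a$aromatic[b$i] & a$aromatic[b$j], 4L, as.integer(b$order))
    bond_block <- sprintf("%3d%3d%3d  0", b$i, b$j, ord)
  }
  out <- c(head, counts, atom_block, bond_block, "M  END")
  if (!all(is.na(a$charge))) {
    out <- c(out, "> <atom.charges>",
             paste(format(a$charge, trim = TRUE), collapse = " "), "")
  }
  writeLines(c(out, "$$$$"), path)
  invisible(path)
}
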