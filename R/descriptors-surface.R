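# Surface and shape descriptors: Shrake-Rupley SASA, grid vdW volume,
# globularity, Vol/SASA, and the hydrophilic (FISA) / pi-carbon (PISA)
# surface partition.

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Quadrature over a deterministic Fibonacci point set on each atom's expanded
#' sphere (radius + probe). A point is accessible if it lies outside every
#' other atom's expanded sphere; the per-atom area is the accessible fraction
#' times the expanded-sphere area.
#'
#' @param mol a [molecule].
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (>= 12; default 960).
#' @return a tibble with one row per atom (`atom`, `element`, `sasa` in A^2)
#'   carrying attributes `total` (A^2), `probe_radius`, `n_points` and
#'   `points` (the accessible surface points, used by [esp_extrema()]).
#' @examples
#' m <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0, radius = 1.7))
#' attr(compute_sasa(m), "total")  # ~ 4*pi*3.1^2
#' @export
compute_sasa <- function(mol, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(mol, "molecule"))
  if (n_points < 12) {
    stop("n_points must be at least 12 for a usable quadrature", call. = FALSE)
  }
  xyz <- mol_xyz(mol)
  r_exp <- mol$atoms$radius + probe_radius
  n <- nrow(xyz)
  unit <- fibonacci_sphere(n_points)
  per_atom <- numeric(n)
  surf_pts <- vector("list", n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    pts <- sweep(unit * r_exp[i], 2, xyz[i, ], "+")
    # neighbours whose expanded sphere can occlude points of atom i
    nb <- which(d2[i, ] < (r_exp[i] + r_exp)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r_exp[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * r_exp[i]^2 * mean(acc)
    surf_pts[[i]] <- pts[acc, , drop = FALSE]
  }
  out <- tibble::tibble(
    atom = seq_len(n),
    element = mol$atoms$element,
    sasa = per_atom
  )
  attr(out, "total") <- sum(per_atom)
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- n_points
  attr(out, "points") <- do.call(rbind, surf_pts)
  class(out) <- c("sasa_result", class(out))
  out
}

#' Total SASA of a molecule
#' @inheritParams compute_sasa
#' @return total solvent-accessible surface area (A^2).
#' @export
sasa_total <- function(mol, probe_radius = 1.4, n_points = 960L) {
  attr(compute_sasa(mol, probe_radius, n_points), "total")
}

#' van der Waals volume by grid counting
#'
#' Counts cubic grid cells whose centre lies inside the union of the atomic
#' vdW spheres over the bounding box of the molecule.
#'
#' @param mol a [molecule].
#' @param grid_spacing cell edge in Angstrom (default 0.2).
#' @return volume in A^3.
#' @export
compute_volume <- function(mol, grid_spacing = 0.2) {
  stopifnot(inherits(mol, "molecule"))
  if (grid_spacing <= 0) stop("grid_spacing must be positive", call. = FALSE)
  xyz <- mol_xyz(mol)
  r <- mol$atoms$radius
  lo <- apply(xyz - r, 2, min) - grid_spacing
  hi <- apply(xyz + r, 2, max) + grid_spacing
  gx <- seq(lo[1] + grid_spacing / 2, hi[1], by = grid_spacing)
  gy <- seq(lo[2] + grid_spacing / 2, hi[2], by = grid_spacing)
  gz <- seq(lo[3] + grid_spacing / 2, hi[3], by = grid_spacing)
  inside <- 0L
  # slice along z to bound memory on larger molecules
  gxy <- as.matrix(expand.grid(x = gx, y = gy))
  for (z in gz) {
    occ <- rep(FALSE, nrow(gxy))
    for (a in seq_len(nrow(xyz))) {
      dz2 <- (z - xyz[a, 3])^2
      if (dz2 > r[a]^2) next
      occ <- occ | ((gxy[, 1] - xyz[a, 1])^2 + (gxy[, 2] - xyz[a, 2])^2 <=
                      r[a]^2 - dz2)
    }
    inside <- inside + sum(occ)
  }
  inside * grid_spacing^3
}

#' Shape descriptors: globularity and Vol/SASA
#'
#' Globularity is the area of the sphere having the molecule's vdW volume,
#' divided by the molecular SASA: `glob = 4*pi*r_eq^2 / SASA` with
#' `r_eq = (3V / 4pi)^(1/3)`. It is 1 for a single sphere probed with a
#' zero-radius probe and decreases as the molecule elongates. `Vol/SASA`
#' (Angstrom) is the companion size-normalised shape measure.
#'
#' @param mol a [molecule].
#' @param probe_radius probe radius used for the SASA (default 1.4).
#' @param n_points SASA quadrature points.
#' @param grid_spacing volume grid spacing.
#' @return a tibble with columns `glob`, `vol_sasa`, `sasa`, `volume`.
#' @export
shape_descriptors <- function(mol, probe_radius = 1.4, n_points = 960L,
                              grid_spacing = 0.2) {
  sasa <- sasa_total(mol, probe_radius, n_points)
  if (sasa <= 0) stop("degenerate input: zero SASA", call. = FALSE)
  vol <- compute_volume(mol, grid_spacing)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  tibble::tibble(
    glob = 4 * pi * r_eq^2 / sasa,
    vol_sasa = vol / sasa,
    sasa = sasa,
    volume = vol
  )
}

#' Hydrophilic and pi-carbon SASA components (FISA / PISA)
#'
#' FISA is the SASA summed over nitrogen and oxygen atoms plus hydrogens
#' bonded to N or O; PISA is the SASA summed over aromatic carbons plus their
#' attached hydrogens. The two atom sets are disjoint, so FISA + PISA never
#' exceeds the total SASA.
#'
#' @param mol a [molecule] with aromatic flags (and bonds, for the attached
#'   hydrogens).
#' @param probe_radius,n_points passed to [compute_sasa()].
#' @return a tibble with columns `fisa`, `pisa`, `sasa` (all A^2).
#' @export
surface_partition <- function(mol, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(mol, "molecule"))
  if (is.null(mol$atoms$aromatic)) {
    stop("molecule lacks aromaticity annotation", call. = FALSE)
  }
  sr <- compute_sasa(mol, probe_radius, n_points)
  el <- mol$atoms$element
  is_no <- el %in% c("N", "O")
  is_aroC <- el == "C" & mol$atoms$aromatic
  h_parent <- rep(NA_integer_, n_atoms(mol))
  if (nrow(mol$bonds) > 0) {
    for (k in which(el == "H")) {
      nb <- bonded_to(mol, k)
      if (length(nb)) h_parent[k] <- nb[1]
    }
  }
  is_h_on_no <- el == "H" & !is.na(h_parent) & is_no[pmax(h_parent, 1)]
  is_h_on_aroC <- el == "H" & !is.na(h_parent) & is_aroC[pmax(h_parent, 1)]
  tibble::tibble(
    fisa = sum(sr$sasa[is_no | is_h_on_no]),
    pisa = sum(sr$sasa[is_aroC | is_h_on_aroC]),
    sasa = attr(sr, "total")
  )
}
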