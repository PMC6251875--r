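# Seeded generators for every input the pipeline needs: planted-signal
# descriptor tables, toy molecules with analytic reference values, constructed
# binding-site geometries at controlled donor distances, orbital-energy
# fixtures, and activity tables shaped like the three study datasets.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a descriptor table with a planted linear structure
#'
#' Descriptors are independent standard normals; the response is
#' `intercept + sum(beta * x) + N(0, noise_sd)`. Decoy descriptors (pure
#' noise, no contribution to the response) are appended to exercise subset
#' search against irrelevant features. At most 3 nonzero coefficients by
#' default, mirroring the size of the published models.
#'
#' @param n_samples number of rows (>= coefficients + 2).
#' @param coefficients named numeric vector of planted coefficients.
#' @param intercept response intercept.
#' @param noise_sd Gaussian noise standard deviation (response units, >= 0).
#' @param n_decoys number of decoy descriptor columns (default 3).
#' @param seed integer seed; recorded in the output attributes.
#' @param max_terms guard on the planted model size (default 3).
#' @return tibble with `id`, the descriptor columns and `response`;
#'   attributes `seed`, `true_coefficients`, `intercept`, `noise_sd`.
#' @export
gen_linear_dataset <- function(n_samples, coefficients, intercept = 0,
                               noise_sd = 0, n_decoys = 3, seed = 1,
                               max_terms = 3) {
  stopifnot(n_samples >= 3, noise_sd >= 0)
  nz <- sum(coefficients != 0)
  if (nz > max_terms) {
    stop("more than ", max_terms, " nonzero planted coefficients",
         call. = FALSE)
  }
  if (n_samples < length(coefficients) + 2) {
    stop("n_samples must be at least number of coefficients + 2",
         call. = FALSE)
  }
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_samples * length(coefficients)),
                nrow = n_samples,
                dimnames = list(NULL, names(coefficients)))
    y <- intercept + drop(X %*% coefficients) +
      stats::rnorm(n_samples, 0, noise_sd)
    D <- matrix(stats::rnorm(n_samples * n_decoys), nrow = n_samples,
                dimnames = list(NULL, paste0("decoy", seq_len(n_decoys))))
    out <- dplyr::bind_cols(
      tibble::tibble(id = sprintf("s%03d", seq_len(n_samples))),
      tibble::as_tibble(X), tibble::as_tibble(D),
      tibble::tibble(response = y)
    )
    attr(out, "seed") <- seed
    attr(out, "true_coefficients") <- coefficients
    attr(out, "intercept") <- intercept
    attr(out, "noise_sd") <- noise_sd
    out
  })
}

ring_coords <- function(n, bond = 1.39) {
  r <- bond / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = r * cos(ang), y = r * sin(ang), z = 0)
}

#' Generate a toy molecule with analytic reference values
#'
#' Kinds: `single_atom` (one sphere; analytic SASA/volume attached as
#' metadata), `pair` (two spheres at a given separation), `linear_chain`
#' (n collinear atoms), `ring` (regular aromatic carbon ring) and
#' `phenol_like` (aromatic 6-ring with one hydroxyl and ring hydrogens;
#' exactly one phenolic O-H donor).
#'
#' @param kind molecule kind (see above).
#' @param radius atomic vdW radius (Angstrom) for generated atoms where a
#'   single radius applies.
#' @param separation sphere separation for `pair` / atom spacing for
#'   `linear_chain` (Angstrom).
#' @param n_atoms chain length or ring size.
#' @param charges optional per-atom partial charges.
#' @param probe_radius probe used for the analytic reference SASA metadata.
#' @return a [molecule]; `single_atom`/`pair` carry `meta$reference_sasa` and
#'   `meta$reference_volume`.
#' @export
gen_toy_molecule <- function(kind = c("single_atom", "pair", "linear_chain",
                                      "ring", "phenol_like"),
                             radius = 1.7, separation = 100, n_atoms = 3,
                             charges = NULL, probe_radius = 1.4) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, separation >= 0)
  mk <- function(atoms, bonds = NULL, name = kind, meta = list()) {
    if (!is.null(charges)) {
      stopifnot(length(charges) == nrow(atoms))
      atoms$charge <- charges
      fc <- round(sum(charges))
    } else fc <- 0
    molecule(atoms, bonds, formal_charge = if (!is.null(charges)) fc else 0,
             name = name, meta = meta)
  }
  switch(kind,
    single_atom = {
      a <- tibble::tibble(element = "C", x = 0, y = 0, z = 0, radius = radius)
      mk(a, meta = list(
        reference_sasa = 4 * pi * (radius + probe_radius)^2,
        reference_volume = 4 / 3 * pi * radius^3
      ))
    },
    pair = {
      a <- tibble::tibble(element = c("C", "C"),
                          x = c(0, separation), y = 0, z = 0,
                          radius = radius)
      overlap <- separation < 2 * (radius + probe_radius)
      mk(a, meta = list(
        reference_sasa = if (!overlap) 2 * 4 * pi * (radius + probe_radius)^2
                         else NA_real_,
        reference_volume = sphere_union_volume(radius, radius, separation)
      ))
    },
    linear_chain = {
      stopifnot(n_atoms >= 2)
      a <- tibble::tibble(element = "C",
                          x = separation * (seq_len(n_atoms) - 1),
                          y = 0, z = 0, radius = radius)
      b <- tibble::tibble(i = seq_len(n_atoms - 1), j = seq_len(n_atoms - 1) + 1,
                          order = 1L)
      mk(a, b)
    },
    ring = {
      stopifnot(n_atoms >= 3)
      xyz <- ring_coords(n_atoms)
      a <- tibble::tibble(element = "C", x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], radius = radius, aromatic = TRUE)
      b <- tibble::tibble(i = seq_len(n_atoms),
                          j = c(seq_len(n_atoms - 1) + 1, 1), order = 1L)
      mk(a, b)
    },
    phenol_like = phenol_like_molecule(charges = charges)
  )
}

# Aromatic 6-ring with one hydroxyl (phenolic O-H) and five ring hydrogens.
phenol_like_molecule <- function(charges = NULL, methoxy = FALSE) {
  ring <- ring_coords(6)
  atoms <- tibble::tibble(
    element = rep("C", 6), x = ring[, 1], y = ring[, 2], z = ring[, 3],
    aromatic = TRUE
  )
  bonds <- tibble::tibble(i = 1:6, j = c(2:6, 1), order = 1L)
  # hydroxyl on C1 (outward along +x), ring H on C2..C6
  r_ring <- sqrt(sum(ring[1, ]^2))
  o_pos <- ring[1, ] * (r_ring + 1.36) / r_ring
  h_pos <- o_pos + c(0, -0.96, 0)
  atoms <- dplyr::bind_rows(
    atoms,
    tibble::tibble(element = "O", x = o_pos[1], y = o_pos[2], z = o_pos[3],
                   aromatic = FALSE),
    tibble::tibble(element = "H", x = h_pos[1], y = h_pos[2], z = h_pos[3],
                   aromatic = FALSE)
  )
  bonds <- dplyr::bind_rows(bonds, tibble::tibble(i = c(1, 7), j = c(7, 8),
                                                  order = 1L))
  for (k in 2:6) {
    hp <- ring[k, ] * (r_ring + 1.09) / r_ring
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      element = "H", x = hp[1], y = hp[2], z = hp[3], aromatic = FALSE))
    bonds <- dplyr::bind_rows(bonds, tibble::tibble(i = k, j = nrow(atoms),
                                                    order = 1L))
  }
  if (methoxy) {
    # methoxy ortho to the hydroxyl, on C2
    o2 <- ring[2, ] * (r_ring + 1.36) / r_ring
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      element = "O", x = o2[1], y = o2[2], z = o2[3], aromatic = FALSE))
    o2_idx <- nrow(atoms)
    c_me <- o2 * (sqrt(sum(o2^2)) + 1.43) / sqrt(sum(o2^2))
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      element = "C", x = c_me[1], y = c_me[2], z = c_me[3], aromatic = FALSE))
    bonds <- dplyr::bind_rows(bonds, tibble::tibble(
      i = c(2, o2_idx), j = c(o2_idx, nrow(atoms)), order = 1L))
    # drop the ring H that was on C2
    h2 <- which(atoms$element == "H" &
                  sapply(seq_len(nrow(atoms)), function(k) {
                    any(bonds$i == 2 & bonds$j == k)
                  }))[1]
    if (!is.na(h2)) {
      keep <- setdiff(seq_len(nrow(atoms)), h2)
      remap <- match(seq_len(nrow(atoms)), keep)
      bonds <- bonds[bonds$i != h2 & bonds$j != h2, ]
      bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
      atoms <- atoms[keep, ]
    }
  }
  if (!is.null(charges)) {
    stopifnot(length(charges) == nrow(atoms))
    atoms$charge <- charges
  }
  molecule(atoms, bonds,
           formal_charge = if (!is.null(charges)) round(sum(charges)) else 0,
           name = if (methoxy) "guaiacol_like" else "phenol_like")
}

#' Analytic volume of a two-sphere union
#'
#' Closed-form union volume of two spheres (lens-overlap subtraction); used
#' as the independent reference for the grid-counting volume.
#'
#' @param r1,r2 sphere radii.
#' @param d centre separation.
#' @return union volume.
#' @export
sphere_union_volume <- function(r1, r2, d) {
  v1 <- 4 / 3 * pi * r1^3
  v2 <- 4 / 3 * pi * r2^3
  if (d >= r1 + r2) return(v1 + v2)
  if (d <= abs(r1 - r2)) return(max(v1, v2))
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  v1 + v2 - lens
}

# Minimal idealized His residue: imidazole ring + NE2 hydrogen + stub CB.
# Built so that HE2 sits at `he2` pointing along `direction`.
build_his_fragment <- function(he2, direction, chain = "A", resid = 458L,
                               ring_plane_perp = c(0, 0, 1)) {
  u <- direction / sqrt(sum(direction^2))
  ne2 <- he2 + 1.01 * u
  # imidazole ring: regular pentagon of bond length 1.37 in the plane
  # spanned by u and ring_plane_perp, with NE2 as one vertex
  rr <- 1.37 / (2 * sin(pi / 5))
  ctr <- ne2 + rr * u
  w <- ring_plane_perp - sum(ring_plane_perp * u) * u
  w <- w / sqrt(sum(w^2))
  verts <- lapply(0:4, function(k) {
    ang <- pi + 2 * pi * k / 5  # vertex 0 back toward NE2
    ctr + rr * (cos(ang) * u + sin(ang) * w)
  })
  names <- c("NE2", "CE1", "ND1", "CG", "CD2")
  el <- c("N", "C", "N", "C", "C")
  cb <- ctr + (rr + 1.5) * u
  tibble::tibble(
    chain = chain, resid = resid, resname = "HIS",
    atom = c(names, "HE2", "CB"),
    element = c(el, "H", "C"),
    x = c(vapply(verts, `[`, numeric(1), 1), he2[1], cb[1]),
    y = c(vapply(verts, `[`, numeric(1), 2), he2[2], cb[2]),
    z = c(vapply(verts, `[`, numeric(1), 3), he2[3], cb[3]),
    occupancy = 1
  )
}

#' Construct a synthetic binding-site pose with controlled geometry
#'
#' Builds a minimal protein fragment — a catalytic His (imidazole with its
#' N-epsilon H), a gate Asp (carboxylate), a T1 Cu marker and optionally a
#' stacking Phe ring — around a phenol-like ligand, such that:
#' the phenolic O sits exactly `donor_distance` from the His N-epsilon H
#' (within 0.01 A); the Asp acceptor O is placed at the requested
#' hydrogen-bond distance/angle from the ligand hydroxyl; and, when
#' `stack_geometry` is given, a Phe ring is placed parallel to the ligand
#' ring at the requested centroid distance and interplanar angle.
#'
#' @param donor_distance phenolic O to N-epsilon H distance (Angstrom, > 0).
#' @param hbond_geometry list `(distance, angle)`: heavy-atom O...O distance
#'   (Angstrom) and D-H...A angle (degrees) of the hydroxyl-to-Asp hydrogen
#'   bond.
#' @param stack_geometry optional list `(distance, angle)` for a Phe ring
#'   above the ligand ring (centroid distance Angstrom, interplanar angle
#'   degrees).
#' @param methoxy add an ortho methoxy group to the ligand (guaiacol-like).
#' @param roles residue-role map for the generated complex.
#' @return a [pose_complex].
#' @export
gen_synthetic_pose <- function(donor_distance,
                               hbond_geometry = list(distance = 2.8,
                                                     angle = 160),
                               stack_geometry = NULL,
                               methoxy = FALSE,
                               roles = tvl_roles) {
  if (donor_distance <= 0) stop("donor_distance must be positive",
                                call. = FALSE)
  lig <- phenol_like_molecule(methoxy = methoxy)
  o_idx <- which(lig$atoms$element == "O")[1]
  O <- c(lig$atoms$x[o_idx], lig$atoms$y[o_idx], lig$atoms$z[o_idx])
  h_idx <- bonded_to(lig, o_idx)
  h_idx <- h_idx[lig$atoms$element[h_idx] == "H"][1]
  H <- c(lig$atoms$x[h_idx], lig$atoms$y[h_idx], lig$atoms$z[h_idx])

  # catalytic His along +x from the phenolic O
  he2 <- O + donor_distance * c(1, 0, 0)
  his <- build_his_fragment(he2, direction = c(1, 0, 0),
                            resid = as.integer(parse_role(
                              roles$catalytic_his)$key))
  # gate Asp carboxylate at the requested H-bond geometry from the hydroxyl
  od1 <- place_by_distance_angle(O, H, hbond_geometry$distance,
                                 hbond_geometry$angle, perp = c(0, 0, 1))
  u_out <- (od1 - H) / dist3(od1, H)
  cg <- od1 + 1.25 * u_out
  # OD2 off at ~120 degrees from the C-OD1 direction, out of plane
  od2 <- cg + 1.25 * (0.5 * u_out + sqrt(3) / 2 * c(0, 0, 1))
  cb <- cg + 1.52 * u_out
  asp <- tibble::tibble(
    chain = "A", resid = as.integer(parse_role(roles$gate_asp)$key),
    resname = "ASP",
    atom = c("OD1", "CG", "OD2", "CB"),
    element = c("O", "C", "O", "C"),
    x = c(od1[1], cg[1], od2[1], cb[1]),
    y = c(od1[2], cg[2], od2[2], cb[2]),
    z = c(od1[3], cg[3], od2[3], cb[3]),
    occupancy = 1
  )
  # T1 copper marker beyond the His ring
  cu_pos <- he2 + (1.01 + 2 * 1.37 / (2 * sin(pi / 5)) + 2.1) * c(1, 0, 0)
  cu <- tibble::tibble(chain = "A", resid = 501L, resname = "CU",
                       atom = "CU", element = "Cu",
                       x = cu_pos[1], y = cu_pos[2], z = cu_pos[3],
                       occupancy = 1)
  protein <- dplyr::bind_rows(his, asp, cu)
  if (!is.null(stack_geometry)) {
    ring_ctr <- c(0, 0, 0)  # ligand ring centroid by construction
    d <- stack_geometry$distance
    ang <- stack_geometry$angle * pi / 180
    ring <- ring_coords(6)
    R <- rotation_matrix(c(1, 0, 0), ang)
    xyz <- ring %*% t(R)
    xyz <- sweep(xyz, 2, ring_ctr + c(0, 0, d), "+")
    phe <- tibble::tibble(
      chain = "A", resid = as.integer(parse_role(roles$stack_residue)$key),
      resname = "PHE",
      atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1
    )
    protein <- dplyr::bind_rows(protein, phe)
  }
  roles_used <- roles[c("gate_asp", "catalytic_his", "t1_cu",
                        if (!is.null(stack_geometry)) "stack_residue")]
  roles_used$t1_cu <- "A/CU"
  pose_complex(protein, lig, roles_used)
}

#' Generate an activity table shaped like the study datasets
#'
#' Shapes mirror the three experimental substrate sets: `A` — 11 structurally
#' diverse TvL substrates with K_m (micromolar, assay pH 4.5); `B` — 16 TvL
#' substrates, 15 congeneric phenols plus one amine, with relative activity
#' (assay pH 9.0); `C` — 23 diverse CuL substrates with K_m (pH 4.5). K_m
#' values are drawn lognormal within 1-10000 micromolar.
#'
#' @param dataset_shape `"A"`, `"B"` or `"C"`.
#' @param seed integer seed.
#' @return tibble of activity records: `id`, `class`, `km_um`,
#'   `relative_activity`, `ph`, `protein`; attribute `seed`.
#' @export
gen_activity_table <- function(dataset_shape = c("A", "B", "C"), seed = 1) {
  dataset_shape <- match.arg(dataset_shape)
  spec <- switch(dataset_shape,
    A = list(n = 11, protein = "TvL", response = "km", ph = 4.5,
             classes = c(rep("phenol", 7), rep("acid", 2), rep("amine", 2))),
    B = list(n = 16, protein = "TvL", response = "activity", ph = 9.0,
             classes = c(rep("phenol", 15), "amine")),
    C = list(n = 23, protein = "CuL", response = "km", ph = 4.5,
             classes = c(rep("phenol", 12), rep("amine", 6), rep("acid", 4),
                         "phosphate"))
  )
  with_seed(seed, {
    rlnorm_trunc <- function(n) {
      v <- stats::rlnorm(n, meanlog = log(150), sdlog = 1.6)
      pmin(pmax(v, 1), 10000)
    }
    out <- tibble::tibble(
      id = sprintf("%s%02d", dataset_shape, seq_len(spec$n)),
      class = spec$classes,
      km_um = if (spec$response == "km") rlnorm_trunc(spec$n) else NA_real_,
      relative_activity = if (spec$response == "activity") {
        stats::rlnorm(spec$n, meanlog = log(50), sdlog = 1)
      } else NA_real_,
      ph = spec$ph,
      protein = spec$protein
    )
    attr(out, "seed") <- seed
    out
  })
}

#' Generate an orbital/total-energy fixture table (hartree)
#'
#' Every row satisfies E(HOMO) < E(LUMO); total energies are constructed
#' Koopmans-consistently (`E_cation - E_neutral = -E_HOMO`, `E_neutral -
#' E_anion = -E_LUMO`) so the orbital and total-energy descriptor routes agree
#' on these fixtures.
#'
#' @param n number of rows (>= 1).
#' @param seed integer seed.
#' @param include_totals also emit neutral/cation/anion total energies.
#' @param include_reference_row append a fixed row with E(HOMO) = -0.30,
#'   E(LUMO) = -0.05 hartree (gap 6.803 eV), handy as a spot check.
#' @return tibble with columns `id`, `e_homo_ha`, `e_lumo_ha` and optionally
#'   the total-energy columns; attribute `seed`.
#' @export
gen_orbital_table <- function(n, seed = 1, include_totals = TRUE,
                              include_reference_row = FALSE) {
  stopifnot(n >= 1)
  with_seed(seed, {
    homo <- stats::runif(n, -0.45, -0.20)
    lumo <- homo + stats::runif(n, 0.05, 0.35)
    out <- tibble::tibble(
      id = sprintf("m%04d", seq_len(n)),
      e_homo_ha = homo, e_lumo_ha = lumo
    )
    if (include_reference_row) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        id = "mref", e_homo_ha = -0.30, e_lumo_ha = -0.05))
    }
    if (include_totals) {
      neutral <- -100 - stats::runif(nrow(out), 0, 50)
      out$e_neutral_ha <- neutral
      out$e_cation_ha <- neutral - out$e_homo_ha
      out$e_anion_ha <- neutral + out$e_lumo_ha
    }
    attr(out, "seed") <- seed
    out
  })
}
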