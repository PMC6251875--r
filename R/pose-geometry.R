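# Protein-ligand pose geometry: donor selection, electron-transfer distance,
# the <5 A active-conformation rule, and interaction fingerprints against a
# residue-role map (gate Asp, catalytic His, T1 Cu, in TvL 1GYC numbering by
# default).

#' Default residue-role map (TvL, PDB 1GYC numbering)
#' @export
tvl_roles <- list(gate_asp = "A/206", catalytic_his = "A/458",
                  stack_residue = "A/265", aux_asn = "A/264", t1_cu = "A/CU")

#' Residue-role map for CuL numbering
#' @export
cul_roles <- list(gate_asp = "A/206", catalytic_his = "A/454",
                  stack_residue = "A/265", aux_asn = "A/264", t1_cu = "A/CU")

parse_role <- function(spec) {
  parts <- strsplit(spec, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("role specifier must be 'chain/resid' or 'chain/RESNAME': ", spec,
         call. = FALSE)
  }
  list(chain = parts[1], key = parts[2])
}

role_rows <- function(protein, spec) {
  p <- parse_role(spec)
  if (grepl("^[0-9]+$", p$key)) {
    which(protein$chain == p$chain & protein$resid == as.integer(p$key))
  } else {
    which(protein$chain == p$chain & protein$resname == p$key)
  }
}

#' Construct a protein-ligand pose complex
#'
#' @param protein data frame of protein atoms with columns `chain`, `resid`,
#'   `resname`, `atom` (PDB atom name), `element`, `x`, `y`, `z` and
#'   optionally `occupancy`.
#' @param ligand a [molecule] (the bound pose).
#' @param roles named list mapping roles (`gate_asp`, `catalytic_his`,
#'   `stack_residue`, `aux_asn`, `t1_cu`) to residue specifiers of the form
#'   `"chain/resid"` or `"chain/RESNAME"`. Defaults to [tvl_roles].
#' @return an object of class `pose_complex`.
#' @export
pose_complex <- function(protein, ligand, roles = tvl_roles) {
  protein <- tibble::as_tibble(protein)
  stopifnot(all(c("chain", "resid", "resname", "atom", "element",
                  "x", "y", "z") %in% names(protein)))
  stopifnot(inherits(ligand, "molecule"))
  for (role in names(roles)) {
    if (length(role_rows(protein, roles[[role]])) == 0) {
      stop("role '", role, "' does not resolve to any residue (",
           roles[[role]], ")", call. = FALSE)
    }
  }
  if ("catalytic_his" %in% names(roles)) {
    his <- protein[role_rows(protein, roles$catalytic_his), ]
    if (!"NE2" %in% his$atom) {
      stop("catalytic_his residue has no NE2 (N-epsilon) atom", call. = FALSE)
    }
  }
  has_h <- any(protein$element == "H") || any(ligand$atoms$element == "H")
  structure(list(protein = protein, ligand = ligand, roles = roles,
                 has_hydrogens = has_h),
            class = "pose_complex")
}

#' @export
print.pose_complex <- function(x, ...) {
  cat("<pose_complex> protein:", nrow(x$protein), "atoms; ligand:",
      nrow(x$ligand$atoms), "atoms; roles:",
      paste(names(x$roles), unlist(x$roles), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Load a pose complex from PDB / SDF files
#'
#' Protein from PDB (via bio3d); when alternate locations are present, the
#' highest-occupancy conformer of each atom is kept (ties: first altLoc code).
#' Ligand from SDF ([read_sdf()]) or from HETATM records of a PDB file.
#'
#' @param protein_pdb path to the protein PDB file.
#' @param ligand_file path to the ligand pose (`.sdf` or `.pdb`).
#' @param roles residue-role map, see [pose_complex()].
#' @return a `pose_complex`.
#' @export
load_complex <- function(protein_pdb, ligand_file, roles = tvl_roles) {
  pdb <- suppressWarnings(bio3d::read.pdb(protein_pdb, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- tibble::as_tibble(pdb$atom)
  # resolve alternate locations: keep the highest-occupancy copy of each atom
  if (any(!is.na(at$alt) & at$alt != "")) {
    at <- at |>
      dplyr::group_by(.data$chain, .data$resno, .data$elety) |>
      dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    message("alternate locations found: kept highest-occupancy conformers")
  }
  protein <- tibble::tibble(
    chain = at$chain, resid = at$resno, resname = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o
  )
  ligand <- if (grepl("\\.sdf$", ligand_file, ignore.case = TRUE)) {
    read_sdf(ligand_file)
  } else {
    lp <- bio3d::read.pdb(ligand_file, verbose = FALSE)$atom
    lp <- lp[lp$type == "HETATM" | TRUE, ]
    molecule(tibble::tibble(
      element = ifelse(is.na(lp$elesy) | lp$elesy == "",
                       substr(trimws(lp$elety), 1, 1), trimws(lp$elesy)),
      x = lp$x, y = lp$y, z = lp$z, name = lp$elety
    ), name = basename(ligand_file))
  }
  pose_complex(protein, ligand, roles)
}

his_reference_atom <- function(complex) {
  his <- complex$protein[role_rows(complex$protein,
                                   complex$roles$catalytic_his), ]
  ne2 <- his[his$atom == "NE2", ][1, ]
  hs <- his[his$element == "H", ]
  if (nrow(hs) > 0) {
    d <- sqrt((hs$x - ne2$x)^2 + (hs$y - ne2$y)^2 + (hs$z - ne2$z)^2)
    if (any(d < 1.25)) {
      h <- hs[which.min(d), ]
      return(list(xyz = c(h$x, h$y, h$z), atom = "NE2-H", is_h = TRUE))
    }
  }
  list(xyz = c(ne2$x, ne2$y, ne2$z), atom = "NE2", is_h = FALSE)
}

#' Select the expected electron-donor atom of a ligand pose
#'
#' Phenolic substrates donate from the hydroxyl oxygen: if the ligand has at
#' least one O-H on an aromatic carbon, the phenolic O closest to the
#' catalytic His N-epsilon (H atom when present) is chosen. Otherwise a
#' primary amine N (>= 2 attached hydrogens) is chosen; otherwise the ligand
#' heavy atom closest to the His reference — a deterministic surrogate for
#' visual selection of the pose closest to the T1 site.
#'
#' @param complex a [pose_complex].
#' @return a one-row tibble: `atom` (ligand atom index), `element`,
#'   `donor_class` (`phenolic_OH`, `amine_NH2` or `nearest_heavy`).
#' @export
select_donor_atom <- function(complex) {
  lig <- complex$ligand
  if (n_atoms(lig) == 0) stop("empty ligand", call. = FALSE)
  ref <- his_reference_atom(complex)$xyz
  el <- lig$atoms$element
  hlist <- attached_hydrogens(lig)
  has_h <- lengths(hlist) > 0
  aro_nb <- vapply(seq_len(n_atoms(lig)), function(k) {
    nb <- bonded_to(lig, k)
    any(lig$atoms$aromatic[nb] & lig$atoms$element[nb] == "C")
  }, logical(1))
  d_ref <- sqrt((lig$atoms$x - ref[1])^2 + (lig$atoms$y - ref[2])^2 +
                  (lig$atoms$z - ref[3])^2)
  pick <- function(idx, class) {
    k <- idx[which.min(d_ref[idx])]
    tibble::tibble(atom = k, element = el[k], donor_class = class)
  }
  phenolic <- which(el == "O" & has_h & aro_nb)
  if (length(phenolic)) return(pick(phenolic, "phenolic_OH"))
  amine <- which(el == "N" & lengths(hlist) >= 2)
  if (length(amine)) return(pick(amine, "amine_NH2"))
  heavy <- which(el != "H")
  pick(heavy, "nearest_heavy")
}

#' Electron-transfer distance from donor atom to the catalytic histidine
#'
#' Euclidean distance from the donor atom to the His N-epsilon hydrogen when
#' hydrogens are present, else to N-epsilon itself (flagged in the result).
#'
#' @param complex a [pose_complex].
#' @param donor one-row tibble from [select_donor_atom()] (default: selected
#'   automatically).
#' @return one-row tibble: `distance` (Angstrom), `reference_atom`
#'   (`"NE2-H"` or `"NE2"`), `donor_atom`, `donor_class`.
#' @export
donor_distance <- function(complex, donor = select_donor_atom(complex)) {
  ref <- his_reference_atom(complex)
  a <- complex$ligand$atoms[donor$atom[1], ]
  tibble::tibble(
    distance = dist3(c(a$x, a$y, a$z), ref$xyz),
    reference_atom = ref$atom,
    donor_atom = donor$atom[1],
    donor_class = donor$donor_class[1]
  )
}

#' Classify a pose as catalytically active by electron-transfer distance
#'
#' A pose is active when the donor-to-His distance is strictly below the
#' threshold (default 5 Angstrom); a distance exactly at the threshold is
#' inactive.
#'
#' @param distance donor-to-His distance (Angstrom), or a tibble from
#'   [donor_distance()].
#' @param threshold cutoff in Angstrom (default 5.0).
#' @return one-row tibble: `distance_to_his`, `threshold`, `is_active`, plus
#'   donor columns when a [donor_distance()] result was supplied.
#' @export
classify_active_pose <- function(distance, threshold = 5.0) {
  extra <- NULL
  if (is.data.frame(distance)) {
    extra <- distance[setdiff(names(distance), "distance")]
    distance <- distance$distance
  }
  if (any(distance <= 0)) stop("distance must be positive", call. = FALSE)
  out <- tibble::tibble(distance_to_his = distance, threshold = threshold,
                        is_active = distance < threshold)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

lig_protein_pairs <- function(complex, rows) {
  p <- complex$protein[rows, ]
  l <- complex$ligand$atoms
  list(p = p, l = l)
}

# protein hydrogens attached to a given protein atom row (by proximity)
protein_attached_h <- function(protein, row, max_d = 1.25) {
  hs <- which(protein$element == "H")
  if (!length(hs)) return(integer(0))
  d <- sqrt((protein$x[hs] - protein$x[row])^2 +
              (protein$y[hs] - protein$y[row])^2 +
              (protein$z[hs] - protein$z[row])^2)
  hs[d < max_d]
}

contact_row <- function(protein, rows_res, type, distance, angle = NA_real_,
                        ligand_atoms, geometry = NA_character_) {
  tibble::tibble(
    chain = protein$chain[rows_res[1]],
    resid = protein$resid[rows_res[1]],
    resname = protein$resname[rows_res[1]],
    contact = type,
    distance = distance,
    angle = angle,
    ligand_atoms = paste(ligand_atoms, collapse = "+"),
    geometry = geometry
  )
}

#' Detect hydrogen bonds between ligand and protein residues
#'
#' Geometric rule: donor-acceptor heavy-atom distance <= `max_dist` and, when
#' the donor hydrogen is present, D-H...A angle >= `min_angle`. Both
#' directions (ligand donor and protein donor) are scanned; N and O atoms act
#' as donors when they carry a hydrogen and as acceptors always.
#'
#' @param complex a [pose_complex].
#' @param residues integer row indices into `complex$protein` to scan
#'   (default: all residues).
#' @param max_dist heavy-atom cutoff (Angstrom, default 3.5).
#' @param min_angle D-H...A angle cutoff (degrees, default 120).
#' @return tibble of contacts (possibly empty): `chain`, `resid`, `resname`,
#'   `contact = "hbond"`, `distance`, `angle`, `ligand_atoms`.
#' @export
detect_hbonds <- function(complex, residues = seq_len(nrow(complex$protein)),
                          max_dist = 3.5, min_angle = 120) {
  pr <- complex$protein
  lig <- complex$ligand
  out <- list()
  p_rows <- residues[pr$element[residues] %in% c("N", "O")]
  l_idx <- which(lig$atoms$element %in% c("N", "O"))
  hlist <- attached_hydrogens(lig)
  for (i in p_rows) {
    P <- c(pr$x[i], pr$y[i], pr$z[i])
    for (k in l_idx) {
      L <- c(lig$atoms$x[k], lig$atoms$y[k], lig$atoms$z[k])
      d <- dist3(P, L)
      if (d > max_dist) next
      # ligand as donor
      ang_l <- NA_real_
      ok <- FALSE
      if (length(hlist[[k]])) {
        for (h in hlist[[k]]) {
          H <- c(lig$atoms$x[h], lig$atoms$y[h], lig$atoms$z[h])
          ang <- angle3(L, H, P)
          if (ang >= min_angle) { ok <- TRUE; ang_l <- ang; break }
        }
      }
      # protein as donor
      if (!ok) {
        phs <- protein_attached_h(pr, i)
        if (length(phs)) {
          for (h in phs) {
            H <- c(pr$x[h], pr$y[h], pr$z[h])
            ang <- angle3(P, H, L)
            if (ang >= min_angle) { ok <- TRUE; ang_l <- ang; break }
          }
        }
      }
      # no hydrogens anywhere: degrade gracefully to the distance criterion
      if (!ok && !length(hlist[[k]]) && !length(protein_attached_h(pr, i))) {
        ok <- TRUE
      }
      if (ok) {
        out[[length(out) + 1]] <-
          contact_row(pr, i, "hbond", d, ang_l, lig$atoms$name[k])
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Detect salt bridges between ligand ammonium groups and carboxylates
#'
#' A ligand nitrogen is treated as charged when it carries >= 3 hydrogens or a
#' positive partial charge > 0.5 e; protein carboxylate oxygens are the
#' OD1/OD2 (Asp) and OE1/OE2 (Glu) atoms. Minimum O...N distance <= `max_dist`
#' declares the bridge.
#'
#' @param complex a [pose_complex].
#' @param residues protein atom row indices to scan.
#' @param max_dist cutoff (Angstrom, default 4.0).
#' @return tibble of `salt_bridge` contacts.
#' @export
detect_salt_bridges <- function(complex,
                                residues = seq_len(nrow(complex$protein)),
                                max_dist = 4.0) {
  pr <- complex$protein
  lig <- complex$ligand
  hlist <- attached_hydrogens(lig)
  q <- lig$atoms$charge
  amm <- which(lig$atoms$element == "N" &
                 (lengths(hlist) >= 3 | (!is.na(q) & q > 0.5)))
  ox <- residues[pr$atom[residues] %in% c("OD1", "OD2", "OE1", "OE2") &
                   pr$resname[residues] %in% c("ASP", "GLU")]
  out <- list()
  for (k in amm) {
    L <- c(lig$atoms$x[k], lig$atoms$y[k], lig$atoms$z[k])
    for (i in ox) {
      d <- dist3(c(pr$x[i], pr$y[i], pr$z[i]), L)
      if (d <= max_dist) {
        out[[length(out) + 1]] <-
          contact_row(pr, i, "salt_bridge", d, NA_real_, lig$atoms$name[k])
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) {
    # one bridge per residue-nitrogen pair: keep the shortest O...N
    res <- res |>
      dplyr::group_by(.data$chain, .data$resid, .data$ligand_atoms) |>
      dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  res
}

protein_ring_atoms <- list(
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

ring_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

# connected components of the ligand aromatic subgraph -> list of atom sets
ligand_rings <- function(lig) {
  aro <- which(lig$atoms$aromatic)
  if (length(aro) < 3) return(list())
  comp <- rep(NA_integer_, n_atoms(lig))
  cid <- 0
  for (s in aro) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    stack <- s; comp[s] <- cid
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      nb <- bonded_to(lig, v)
      nb <- nb[nb %in% aro & is.na(comp[nb])]
      comp[nb] <- cid
      stack <- c(stack, nb)
    }
  }
  grp <- split(seq_len(n_atoms(lig))[!is.na(comp)], comp[!is.na(comp)])
  grp[lengths(grp) >= 3]
}

#' Detect pi-pi stacking between ligand and protein aromatic rings
#'
#' Ring-centroid distance <= `max_dist` with an interplanar angle <= 30
#' degrees (face-to-face) or between 60 and 90 degrees (edge-to-face);
#' intermediate tilts are not reported as contacts.
#'
#' @param complex a [pose_complex].
#' @param residues protein atom row indices to scan.
#' @param max_dist centroid-centroid cutoff (Angstrom, default 5.5).
#' @return tibble of `pipi` contacts with `geometry` `"face"` or `"edge"`.
#' @export
detect_pipi <- function(complex, residues = seq_len(nrow(complex$protein)),
                        max_dist = 5.5) {
  pr <- complex$protein
  lig <- complex$ligand
  lrings <- ligand_rings(lig)
  if (!length(lrings)) return(dplyr::bind_rows(list()))
  res_keys <- unique(paste(pr$chain[residues], pr$resid[residues]))
  out <- list()
  for (key in res_keys) {
    rows <- residues[paste(pr$chain[residues], pr$resid[residues]) == key]
    resname <- pr$resname[rows[1]]
    ring_names <- protein_ring_atoms[[resname]]
    if (is.null(ring_names)) next
    rrows <- rows[pr$atom[rows] %in% ring_names]
    if (length(rrows) < length(ring_names)) next
    pp <- ring_plane(as.matrix(pr[rrows, c("x", "y", "z")]))
    for (ring in lrings) {
      lp <- ring_plane(mol_xyz(lig)[ring, , drop = FALSE])
      d <- dist3(pp$centroid, lp$centroid)
      if (d > max_dist) next
      cosang <- abs(sum(pp$normal * lp$normal))
      ang <- acos(pmin(1, cosang)) * 180 / pi
      geom <- if (ang <= 30) "face" else if (ang >= 60) "edge" else NA
      if (is.na(geom)) next
      out[[length(out) + 1]] <-
        contact_row(pr, rrows, "pipi", d, ang,
                    lig$atoms$name[ring], geometry = geom)
    }
  }
  dplyr::bind_rows(out)
}

#' Interaction fingerprint and active-pose call for a complex
#'
#' Runs the hydrogen-bond, salt-bridge and pi-pi detectors over the role
#' residues plus every residue with an atom within `contact_radius` of the
#' ligand, orders contacts deterministically (residue id, then contact type),
#' and appends the electron-transfer active-pose call.
#'
#' @param complex a [pose_complex].
#' @param contact_radius residue inclusion radius around the ligand
#'   (Angstrom, default 4.5).
#' @param active_threshold donor-distance cutoff (Angstrom, default 5.0).
#' @return a tibble of contacts (class `pose_fingerprint`) with attribute
#'   `active_call` (the [classify_active_pose()] row).
#' @export
build_fingerprint <- function(complex, contact_radius = 4.5,
                              active_threshold = 5.0) {
  pr <- complex$protein
  lxyz <- mol_xyz(complex$ligand)
  near <- vapply(seq_len(nrow(pr)), function(i) {
    min((lxyz[, 1] - pr$x[i])^2 + (lxyz[, 2] - pr$y[i])^2 +
          (lxyz[, 3] - pr$z[i])^2) <= contact_radius^2
  }, logical(1))
  role_r <- unlist(lapply(complex$roles, function(s) role_rows(pr, s)))
  keys <- unique(paste(pr$chain, pr$resid)[near | seq_len(nrow(pr)) %in% role_r])
  rows <- which(paste(pr$chain, pr$resid) %in% keys)
  fp <- dplyr::bind_rows(
    detect_hbonds(complex, rows),
    detect_salt_bridges(complex, rows),
    detect_pipi(complex, rows)
  )
  if (nrow(fp) > 0) {
    fp <- dplyr::arrange(fp, .data$chain, .data$resid, .data$contact,
                         .data$distance)
  } else {
    fp <- tibble::tibble(chain = character(), resid = integer(),
                         resname = character(), contact = character(),
                         distance = numeric(), angle = numeric(),
                         ligand_atoms = character(), geometry = character())
  }
  call <- classify_active_pose(donor_distance(complex),
                               threshold = active_threshold)
  attr(fp, "active_call") <- call
  class(fp) <- c("pose_fingerprint", class(fp))
  fp
}

#' Apply a rigid transform jointly to protein and ligand
#' @param complex a [pose_complex].
#' @param transform list with `R` and `t`, see [random_rigid_transform()].
#' @return the transformed complex.
#' @export
transform_complex <- function(complex, transform) {
  xyz <- apply_rigid(as.matrix(complex$protein[, c("x", "y", "z")]), transform)
  complex$protein$x <- xyz[, 1]
  complex$protein$y <- xyz[, 2]
  complex$protein$z <- xyz[, 3]
  complex$ligand <- transform_molecule(complex$ligand, transform)
  complex
}

#' Write a pose complex to a PDB file
#'
#' Protein atoms as ATOM records (metals as HETATM), ligand atoms as HETATM
#' records with residue name LIG. Coordinates in Angstrom.
#'
#' @param complex a [pose_complex].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_pdb <- function(complex, path) {
  pr <- complex$protein
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  rec <- ifelse(pr$resname %in% aa3, "ATOM  ", "HETATM")
  fmt <- function(record, serial, name, resn, chain, resid, x, y, z, elem) {
    sprintf("%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            record, serial, substr(name, 1, 4), resn, chain, resid,
            x, y, z, elem)
  }
  lines <- fmt(rec, seq_len(nrow(pr)), pr$atom, pr$resname, pr$chain,
               pr$resid, pr$x, pr$y, pr$z, pr$element)
  la <- complex$ligand$atoms
  lig_lines <- fmt("HETATM", nrow(pr) + seq_len(nrow(la)), la$name, "LIG",
                   "L", 1L, la$x, la$y, la$z, la$element)
  writeLines(c(lines, lig_lines, "END"), path)
  invisible(path)
}
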