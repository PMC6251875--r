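# Octanol-water partition / aqueous solubility analogues, hydrogen-bond
# acceptor counting and electrostatic-potential extrema.

# Condensed atom-contribution table for the logP analogue ("lacqsar.clogp.v1").
# Atom typing collapses the classic fragment schemes to ten types resolvable
# from elements, bonds and aromatic flags alone. Contributions in log units.
clogp_contrib <- c(
  H_C    =  0.123,   # H on carbon
  H_NO   = -0.268,   # H on nitrogen/oxygen
  C_sp3  =  0.144,   # aliphatic C bonded only to C/H
  C_het  = -0.204,   # aliphatic C with >= 1 heteroatom neighbour
  C_ar   =  0.158,   # aromatic C
  O_OH   = -0.289,   # hydroxyl O
  O_eth  = -0.068,   # ether / aromatic-substituent O without H
  O_carb = -0.117,   # carbonyl-type O (double bond)
  N_any  = -0.601,   # nitrogen
  S_any  =  0.255,
  F_any  =  0.420,
  Cl_any =  0.690,
  Br_any =  0.887,
  P_any  =  0.800
)

atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                   P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.90,
                   Na = 22.990, Cu = 63.546)

clogp_atom_type <- function(mol, k) {
  el <- mol$atoms$element[k]
  nb <- bonded_to(mol, k)
  nb_el <- mol$atoms$element[nb]
  switch(el,
    H = if (any(nb_el %in% c("N", "O"))) "H_NO" else "H_C",
    C = if (mol$atoms$aromatic[k]) "C_ar"
        else if (any(!nb_el %in% c("C", "H"))) "C_het" else "C_sp3",
    O = {
      dbl <- any(mol$bonds$order[(mol$bonds$i == k | mol$bonds$j == k)] >= 2)
      if (any(nb_el == "H")) "O_OH" else if (dbl) "O_carb" else "O_eth"
    },
    N = "N_any", S = "S_any", F = "F_any", Cl = "Cl_any", Br = "Br_any",
    P = "P_any",
    stop("no logP contribution for atom ", k, " (element ", el, ")",
         call. = FALSE)
  )
}

count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(0L)
  ring <- ring_bond_flags(mol)
  heavy_deg <- vapply(seq_len(n_atoms(mol)), function(k) {
    sum(mol$atoms$element[bonded_to(mol, k)] != "H")
  }, numeric(1))
  is_heavy <- mol$atoms$element != "H"
  sum(b$order == 1 & !ring &
        is_heavy[b$i] & is_heavy[b$j] &
        heavy_deg[b$i] >= 2 & heavy_deg[b$j] >= 2)
}

#' Octanol-water partition and aqueous solubility analogues
#'
#' `logp`: additive atom-contribution estimate of log Po/w using the package's
#' condensed ten-type contribution table (scheme tag in the result metadata) —
#' an analogue of, not a reimplementation of, the commercial QPlogPo/w
#' descriptor. `logs`: aqueous solubility (log mol/L) from the published ESOL
#' regression, `0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP` with MW the
#' molecular weight, RB the rotatable-bond count and AP the aromatic
#' proportion of heavy atoms.
#'
#' @param mol a [molecule] with bonds and aromatic flags.
#' @return a tibble with columns `logp`, `logs`, `mw`, `rotatable_bonds`,
#'   `aromatic_proportion`; attribute `scheme` names the contribution table.
#' @export
logp_logs <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  types <- vapply(seq_len(n_atoms(mol)), function(k) clogp_atom_type(mol, k),
                  character(1))
  logp <- sum(clogp_contrib[types])
  mw <- sum(atomic_masses[mol$atoms$element], na.rm = TRUE)
  rb <- count_rotatable_bonds(mol)
  heavy <- mol$atoms$element != "H"
  ap <- if (any(heavy)) mean(mol$atoms$aromatic[heavy]) else 0
  logs <- 0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rb - 0.74 * ap
  out <- tibble::tibble(logp = logp, logs = logs, mw = mw,
                        rotatable_bonds = rb, aromatic_proportion = ap)
  attr(out, "scheme") <- c(logp = "lacqsar.clogp.v1", logs = "ESOL")
  out
}

#' Rule-based hydrogen-bond acceptor count
#'
#' Counts N and O atoms with available lone pairs. Rules: every O counts 1,
#' except that the terminal O pair of a carboxyl(ate)/nitro-like group (two O
#' atoms on one common heavy atom, at least one double-bonded) jointly counts
#' 1; N counts 1 unless it is an amide N (bonded to a carbonyl C), an aromatic
#' N carrying an H, or positively charged / four-coordinate.
#'
#' @param mol a [molecule] with bonds.
#' @return acceptor count (numeric; integral under these rules).
#' @export
count_hb_acceptors <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  el <- mol$atoms$element
  b <- mol$bonds
  has_dbl_O <- function(k) {
    rows <- which((b$i == k | b$j == k) & b$order >= 2)
    any(el[setdiff(c(b$i[rows], b$j[rows]), k)] == "O")
  }
  count <- 0
  counted_O <- rep(FALSE, n_atoms(mol))
  # carboxyl / nitro style duplication: two O on a common parent count once
  for (k in which(!el %in% "H")) {
    o_nb <- bonded_to(mol, k)
    o_nb <- o_nb[el[o_nb] == "O"]
    terminal_o <- o_nb[vapply(o_nb, function(o) {
      all(el[setdiff(bonded_to(mol, o), k)] %in% "H")
    }, logical(1))]
    if (length(terminal_o) >= 2 && has_dbl_O(k)) {
      count <- count + 1
      counted_O[terminal_o] <- TRUE
    }
  }
  for (k in which(el == "O" & !counted_O)) count <- count + 1
  for (k in which(el == "N")) {
    nb <- bonded_to(mol, k)
    amide <- any(vapply(nb[el[nb] == "C"], has_dbl_O, logical(1)))
    arNH <- mol$atoms$aromatic[k] && any(el[nb] == "H")
    positive <- (!is.na(mol$atoms$charge[k]) && mol$atoms$charge[k] > 0.5) ||
      length(nb) >= 4
    if (!amide && !arNH && !positive) count <- count + 1
  }
  count
}

#' Electrostatic-potential extrema on the accessible surface
#'
#' Coulomb potential of the atomic point charges evaluated at every
#' solvent-accessible surface point (unit positive probe charge), using the
#' conversion constant 332.0636 kcal A / (mol e^2). The maximum and minimum
#' over the surface are returned together with their coordinates.
#'
#' @param mol a [molecule] with partial charges.
#' @param probe_radius,n_points surface construction, as [compute_sasa()].
#' @return a tibble with columns `esp_max`, `esp_min` (kcal/mol); attributes
#'   `max_point` and `min_point` give the surface coordinates.
#' @export
esp_extrema <- function(mol, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(mol, "molecule"))
  q <- mol$atoms$charge
  if (all(is.na(q))) stop("molecule has no partial charges", call. = FALSE)
  q[is.na(q)] <- 0
  sr <- compute_sasa(mol, probe_radius, n_points)
  pts <- attr(sr, "points")
  if (is.null(pts) || nrow(pts) == 0) {
    stop("no accessible surface points (buried molecule?)", call. = FALSE)
  }
  xyz <- mol_xyz(mol)
  pot <- numeric(nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    if (q[a] == 0) next
    d <- sqrt((pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
                (pts[, 3] - xyz[a, 3])^2)
    pot <- pot + 332.0636 * q[a] / d
  }
  i_max <- which.max(pot); i_min <- which.min(pot)
  out <- tibble::tibble(esp_max = pot[i_max], esp_min = pot[i_min])
  attr(out, "max_point") <- pts[i_max, ]
  attr(out, "min_point") <- pts[i_min, ]
  out
}
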