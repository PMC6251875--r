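# Conceptual-DFT reactivity descriptors from supplied orbital or total
# energies. This module never runs a quantum-chemistry calculation; energies
# come from an external engine and are consumed as inputs.

#' Hartree to electron-volt conversion constant
#' @export
HARTREE_TO_EV <- 27.2114

finalize_electronic <- function(ip, ea, gap, mode) {
  chi <- (ip + ea) / 2
  tibble::tibble(
    ip = ip, ea = ea,
    electronegativity = chi,
    hardness = (ip - ea) / 2,
    chemical_potential = -chi,
    gap = gap,
    mode = mode
  )
}

#' Electronic descriptors by the Koopmans approximation
#'
#' From orbital energies: IP = -E(HOMO), EA = -E(LUMO), electronegativity
#' chi = (IP + EA)/2, hardness eta = (IP - EA)/2, chemical potential mu =
#' -chi, gap = E(LUMO) - E(HOMO). Inputs in hartree, outputs in eV
#' (conversion 27.2114 eV/Ha). Vectorised over rows of a data frame.
#'
#' @param energies data frame with columns `e_homo_ha` and `e_lumo_ha`
#'   (hartree); any other columns (e.g. an `id`) are carried through.
#' @return a tibble: input id columns plus `ip`, `ea`, `electronegativity`,
#'   `hardness`, `chemical_potential`, `gap` (all eV) and `mode`.
#' @examples
#' koopmans_descriptors(data.frame(e_homo_ha = -0.30, e_lumo_ha = -0.05))
#' @export
koopmans_descriptors <- function(energies) {
  energies <- tibble::as_tibble(energies)
  stopifnot(all(c("e_homo_ha", "e_lumo_ha") %in% names(energies)))
  if (any(energies$e_homo_ha >= energies$e_lumo_ha)) {
    stop("E(HOMO) must be below E(LUMO) in every row", call. = FALSE)
  }
  ip <- -energies$e_homo_ha * HARTREE_TO_EV
  ea <- -energies$e_lumo_ha * HARTREE_TO_EV
  gap <- (energies$e_lumo_ha - energies$e_homo_ha) * HARTREE_TO_EV
  dplyr::bind_cols(
    energies[setdiff(names(energies), c("e_homo_ha", "e_lumo_ha"))],
    finalize_electronic(ip, ea, gap, "koopmans")
  )
}

#' Electronic descriptors from total-energy differences
#'
#' Vertical route for systems whose orbital energies are unreliable (e.g.
#' anions): IP = E(cation) - E(neutral), EA = E(neutral) - E(anion), in
#' hartree, converted to eV. The HOMO-LUMO gap is reported only when orbital
#' energies are also present.
#'
#' @param energies data frame with columns `e_neutral_ha`, `e_cation_ha` and
#'   optionally `e_anion_ha`, `e_homo_ha`, `e_lumo_ha`.
#' @return a tibble as [koopmans_descriptors()], `mode = "delta_e"`; `ea` and
#'   dependent quantities are `NA` where `e_anion_ha` is missing.
#' @export
delta_e_descriptors <- function(energies) {
  energies <- tibble::as_tibble(energies)
  missing <- setdiff(c("e_neutral_ha", "e_cation_ha"), names(energies))
  if (length(missing)) {
    stop("missing required total-energy columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ip <- (energies$e_cation_ha - energies$e_neutral_ha) * HARTREE_TO_EV
  ea <- if ("e_anion_ha" %in% names(energies)) {
    (energies$e_neutral_ha - energies$e_anion_ha) * HARTREE_TO_EV
  } else rep(NA_real_, nrow(energies))
  gap <- if (all(c("e_homo_ha", "e_lumo_ha") %in% names(energies))) {
    (energies$e_lumo_ha - energies$e_homo_ha) * HARTREE_TO_EV
  } else rep(NA_real_, nrow(energies))
  keep <- setdiff(names(energies),
                  c("e_neutral_ha", "e_cation_ha", "e_anion_ha",
                    "e_homo_ha", "e_lumo_ha"))
  dplyr::bind_cols(energies[keep], finalize_electronic(ip, ea, gap, "delta_e"))
}

#' Read an orbital/total energy table from CSV
#'
#' Expected columns: `id`, `e_homo_ha`, `e_lumo_ha` and optionally
#' `e_neutral_ha`, `e_cation_ha`, `e_anion_ha` (all hartree).
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_energy_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
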