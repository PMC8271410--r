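# Default hydrophobic amino-acid set; configurable because published
# hydrophobic ratios are not always derivable from a single convention.
HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE",
                          "MET", "TRP")

# Cofactors appear in contact tables (e.g. FAD271) but are not amino acids.
COFACTOR_CODES <- c("FAD", "NAD", "NDP", "FMN", "HEM", "ADP", "ATP")

#' Summary statistics of a protein-ligand contact table
#'
#' Mean contact distance over every listed distance (a residue with two
#' recorded contacts contributes twice), halogen-bond count (bond type
#' `"Br"`), distinct residue count, and the hydrophobic fraction over
#' distinct amino-acid residues (cofactors such as FAD enter the distance
#' statistics but are excluded from amino-acid counts).
#'
#' @param table Interaction records for one ligand/receptor pair
#'   (columns `residue, distance_A, bond_type`; see [read_interactions()]).
#' @param hydrophobic_set Three-letter codes counted as hydrophobic.
#' @return List of class `bond_stats`: `n_contacts`, `mean_distance`,
#'   `halogen_bonds`, `n_residues`, `hydrophobic_fraction`,
#'   `hydrophobic_residues`.
#' @export
bond_stats <- function(table, hydrophobic_set = HYDROPHOBIC_RESIDUES) {
  if (nrow(table) == 0L) stop("empty interaction table")
  if (any(table$distance_A <= 0)) stop("distances must be positive")
  code <- substr(table$residue, 1, 3)
  amino <- !(code %in% COFACTOR_CODES)
  res <- unique(table$residue[amino])
  hyd <- res[substr(res, 1, 3) %in% hydrophobic_set]
  structure(list(
    n_contacts = nrow(table),
    mean_distance = mean(table$distance_A),
    halogen_bonds = sum(table$bond_type == "Br"),
    n_residues = length(res),
    hydrophobic_fraction = if (length(res)) length(hyd) / length(res) else NA_real_,
    hydrophobic_residues = hyd), class = "bond_stats")
}

#' Percent decrease in mean contact distance across a modification
#'
#' `(mean_before - mean_after) / mean_before * 100`, computed on unrounded
#' means. A shorter mean contact distance indicates tighter binding and
#' hence stronger degradability.
#'
#' @param before,after `bond_stats` for the template and the derivative.
#' @return Percent decrease (positive = contacts got shorter).
#' @export
length_change <- function(before, after) {
  if (!is.finite(before$mean_distance) || before$mean_distance <= 0)
    stop("reference mean distance must be positive")
  (before$mean_distance - after$mean_distance) / before$mean_distance * 100
}

#' MM/PBSA binding free-energy ledger
#'
#' End-state bookkeeping: `G_bind = G_complex - G_free_protein -
#' G_free_ligand`; each species' free energy in solution decomposes as
#' `G = E_gas - T*S_gas + G_solvation` with `G_solvation = G_polar +
#' G_nonpolar`. When a per-term ledger (van der Waals, electrostatic, polar
#' solvation, SASA, SAV, WCA, ...) is supplied together with a total, the
#' sum identity is validated to 0.01 kJ/mol.
#'
#' @param g_complex,g_protein,g_ligand Free energies of the complex and the
#'   free species (kJ/mol).
#' @param e_gas,ts_gas,g_polar,g_nonpolar Optional gas/solvation split of
#'   the binding free energy.
#' @param terms Optional named numeric vector of energy terms.
#' @param total Optional total the `terms` must sum to (defaults to
#'   `g_bind` when omitted and the split is absent).
#' @param tolerance Ledger-sum tolerance, kJ/mol.
#' @return List of class `energy_decomposition` with `g_bind`, the optional
#'   `g` (from the gas/solvation split), `g_solvation`, and the validated
#'   `terms`.
#' @export
mmpbsa_ledger <- function(g_complex, g_protein, g_ligand,
                          e_gas = NULL, ts_gas = NULL,
                          g_polar = NULL, g_nonpolar = NULL,
                          terms = NULL, total = NULL, tolerance = 0.01) {
  vals <- c(g_complex, g_protein, g_ligand)
  if (any(!is.finite(vals))) stop("non-finite species free energies")
  g_bind <- g_complex - g_protein - g_ligand
  g_solv <- NULL; g <- NULL
  if (!is.null(g_polar) || !is.null(g_nonpolar)) {
    if (is.null(g_polar) || is.null(g_nonpolar))
      stop("supply both g_polar and g_nonpolar, or neither")
    g_solv <- g_polar + g_nonpolar
  }
  if (!is.null(e_gas)) {
    if (is.null(ts_gas)) ts_gas <- 0
    g <- e_gas - ts_gas + (if (is.null(g_solv)) 0 else g_solv)
  }
  if (!is.null(terms)) {
    if (is.null(names(terms)) || any(!nzchar(names(terms))))
      stop("energy terms must be named")
    tot <- if (!is.null(total)) total else g_bind
    resid <- sum(terms) - tot
    if (abs(resid) > tolerance)
      stop(sprintf("term ledger does not sum to total: residual %.4f kJ/mol",
                   resid))
  }
  structure(list(g_bind = g_bind, g = g, g_solvation = g_solv,
                 g_polar = g_polar, g_nonpolar = g_nonpolar, terms = terms),
            class = "energy_decomposition")
}

#' Per-term change rates between two energy decompositions
#'
#' `(after - before) / |before| * 100` per matching term; a strengthening
#' (more negative) term yields a negative rate. Terms at zero before and
#' after report 0; a zero-before, nonzero-after term is flagged undefined
#' and excluded from the largest-rate identification.
#'
#' @param before,after `energy_decomposition` objects (or named vectors)
#'   with matching term ledgers.
#' @return Data frame `term, before, after, rate_pct, undefined`, with
#'   attribute `largest` naming the largest-magnitude defined rate.
#' @export
term_change_rates <- function(before, after) {
  tb <- if (inherits(before, "energy_decomposition")) before$terms else before
  ta <- if (inherits(after, "energy_decomposition")) after$terms else after
  if (is.null(tb) || is.null(ta)) stop("both inputs need term ledgers")
  if (!setequal(names(tb), names(ta)))
    stop("term ledgers do not match: ",
         paste(union(setdiff(names(tb), names(ta)),
                     setdiff(names(ta), names(tb))), collapse = ", "))
  ta <- ta[names(tb)]
  undef <- tb == 0 & ta != 0
  rate <- ifelse(tb == 0 & ta == 0, 0,
                 ifelse(undef, NA_real_, (ta - tb) / abs(tb) * 100))
  out <- data.frame(term = names(tb), before = unname(tb), after = unname(ta),
                    rate_pct = unname(rate), undefined = unname(undef))
  defined <- which(!out$undefined)
  attr(out, "largest") <-
    if (length(defined)) out$term[defined[which.max(abs(out$rate_pct[defined]))]]
    else NA_character_
  out
}
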