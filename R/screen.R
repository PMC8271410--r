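#' Relative change in percent
#'
#' `(value - reference) / reference * 100`, the "Relative Error (%)" columns
#' of the derivative prediction and environmental tables.
#'
#' @param value Numeric vector.
#' @param reference Nonzero reference value(s).
#' @param digits Rounding for display (default 2; pass `NA` for unrounded).
#' @return Percent change(s).
#' @export
relative_change <- function(value, reference, digits = 2) {
  if (any(reference == 0)) stop("zero reference in relative_change")
  out <- (value - reference) / reference * 100
  if (!is.na(digits)) out <- round(out, digits)
  out
}

#' Functional screen of designed derivatives
#'
#' Selects the derivatives predicted to beat the template molecule in all
#' three QSAR models simultaneously: the synergy model (CM) and both
#' single-factor models (PM, plant; MM, microbial). Strict inequality, so
#' the template never passes against itself.
#'
#' @param preds Data frame with columns `molecule_id, CM, PM, MM`
#'   (see [read_predictions()]).
#' @param template Template molecule id (default `"BDEs-3"`).
#' @return Character vector of selected ids, with attribute `ledger` (data
#'   frame of per-model booleans).
#' @export
functional_screen <- function(preds, template = "BDEs-3") {
  need <- c("CM", "PM", "MM")
  miss <- setdiff(need, names(preds))
  if (length(miss)) stop("missing model column(s): ", paste(miss, collapse = ", "))
  if (!template %in% preds$molecule_id)
    stop("template molecule ", template, " not in table")
  ref <- preds[preds$molecule_id == template, need]
  cand <- preds[preds$molecule_id != template, , drop = FALSE]
  ok <- sapply(need, function(m) cand[[m]] > ref[[m]])
  ok <- matrix(ok, nrow = nrow(cand), dimnames = list(NULL, need))
  sel <- cand$molecule_id[rowSums(ok) == length(need)]
  structure(sel, ledger = data.frame(molecule_id = cand$molecule_id, ok,
                                     pass = rowSums(ok) == length(need)))
}

#' Environmental-friendliness and functionality screen
#'
#' Compares each derivative against the template on four endpoints:
#' flame retardancy maintained (C-Br bond dissociation enthalpy `>=`
#' template), lower toxicity (EC50 strictly below), lower bioconcentration
#' (log BCF strictly below) and lower long-range transport (vapor pressure
#' strictly below). Derivatives flagged insoluble (EPI-unmeasurable) are
#' excluded from the EC50 comparison but still screened on the remaining
#' endpoints; they can never reach the final pass set and carry reason code
#' `"insoluble"` in the ledger.
#'
#' @param profiles Data frame from [read_env_profiles()].
#' @param template Template molecule id (default `"BDEs-3"`).
#' @return List: `selected` (ids passing all criteria), `counts` (named
#'   vector, number of measurable derivatives passing each criterion),
#'   `ledger` (per-derivative booleans and reason codes).
#' @export
environmental_screen <- function(profiles, template = "BDEs-3") {
  if (!template %in% profiles$molecule_id)
    stop("template molecule ", template, " not in table")
  meas <- !profiles$insoluble
  if (any(profiles$ec50_mg_l[meas] <= 0, na.rm = TRUE) ||
      any(profiles$vp_pa <= 0, na.rm = TRUE))
    stop("EC50 and vapor pressure must be positive where measurable")
  ref <- profiles[profiles$molecule_id == template, ]
  cand <- profiles[profiles$molecule_id != template, , drop = FALSE]

  flame <- cand$cbr_bde_kcal_mol >= ref$cbr_bde_kcal_mol
  tox <- !cand$insoluble & cand$ec50_mg_l < ref$ec50_mg_l
  bcf <- !cand$insoluble & cand$log_bcf < ref$log_bcf
  vp <- !cand$insoluble & cand$vp_pa < ref$vp_pa
  pass <- flame & tox & bcf & vp

  ledger <- data.frame(molecule_id = cand$molecule_id,
                       flame_retardancy = flame, toxicity = tox,
                       bioconcentration = bcf, vapor_pressure = vp,
                       pass = pass,
                       reason = ifelse(cand$insoluble, "insoluble", ""))
  list(selected = cand$molecule_id[pass],
       counts = c(flame_retardancy = sum(flame[!cand$insoluble]),
                  toxicity = sum(tox), bioconcentration = sum(bcf),
                  vapor_pressure = sum(vp),
                  measurable = sum(!cand$insoluble)),
       ledger = ledger)
}

#' Standard enthalpy of a species from DFT components
#'
#' `H298 = E + ZPE + H_trans + H_rot + H_vib + RT`; every term must carry
#' the same declared unit.
#'
#' @param E Electronic energy.
#' @param zpe Zero-point energy correction.
#' @param h_trans,h_rot,h_vib Translational, rotational and vibrational
#'   thermal contributions.
#' @param temperature Kelvin (default 298.15).
#' @param unit One of `"kcal/mol"`, `"kJ/mol"`, `"hartree"`.
#' @return Object of class `enthalpy`: list with `value` and `unit`.
#' @export
species_enthalpy <- function(E, zpe = 0, h_trans = 0, h_rot = 0, h_vib = 0,
                             temperature = 298.15,
                             unit = c("kcal/mol", "kJ/mol", "hartree")) {
  unit <- match.arg(unit)
  if (temperature <= 0) stop("temperature must be positive (K)")
  rt <- switch(unit,
               "kcal/mol" = 1.987204259e-3 * temperature,
               "kJ/mol" = 8.31446261815e-3 * temperature,
               "hartree" = 3.166811563e-6 * temperature)
  structure(list(value = E + zpe + h_trans + h_rot + h_vib + rt, unit = unit),
            class = "enthalpy")
}

#' C-Br homolytic bond dissociation enthalpy
#'
#' For the reaction `R-Br -> R + Br`,
#' `BDE = H298(R) + H298(Br) - H298(RBr)`; a positive value means the bond
#' resists homolysis (the flame-retardancy indicator used to rank designed
#' derivatives).
#'
#' @param r,br,rbr `enthalpy` objects from [species_enthalpy()] for the
#'   radical R, the bromine atom and the parent molecule RBr. All three must
#'   share one unit.
#' @return Bond dissociation enthalpy in that unit.
#' @export
bond_dissociation_enthalpy <- function(r, br, rbr) {
  parts <- list(r = r, br = br, rbr = rbr)
  if (!all(vapply(parts, inherits, logical(1), "enthalpy")))
    stop("all inputs must be 'enthalpy' objects (species_enthalpy)")
  units <- vapply(parts, `[[`, character(1), "unit")
  if (length(unique(units)) != 1L)
    stop("mixed units: ", paste(names(parts), units, sep = "=", collapse = ", "))
  r$value + br$value - rbr$value
}

#' Convert an enthalpy between unit systems
#' @param x An `enthalpy` object.
#' @param unit Target unit.
#' @return An `enthalpy` in the target unit.
#' @export
convert_enthalpy <- function(x, unit = c("kcal/mol", "kJ/mol", "hartree")) {
  unit <- match.arg(unit)
  to_kcal <- c("kcal/mol" = 1, "kJ/mol" = 1 / 4.184,
               "hartree" = 627.509474)
  v <- x$value * to_kcal[[x$unit]] / to_kcal[[unit]]
  structure(list(value = v, unit = unit), class = "enthalpy")
}
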