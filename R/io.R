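#' Path to a packaged fixture
#'
#' The worked tables of the study ship as plain CSV under `extdata`:
#' `table1_scores.csv` (177 docked PBDEs with plant PS and microbial MS
#' LibDock scores), `table1_printed_cs.csv` (the published composite column,
#' for regression comparison), `table3_predictions.csv`,
#' `table4_env.csv`, `table5_snr.csv`, `table6_responses.csv`,
#' `table7_interactions.csv`.
#'
#' @param file Fixture file name.
#' @return Absolute path.
#' @export
synergy_fixture <- function(file) {
  p <- system.file("extdata", file, package = "pbdesynergy")
  if (p == "") stop("no packaged fixture named ", file)
  p
}

# Read a CSV defensively: UTF-8, U+2212 minus normalized to ASCII hyphen.
read_csv_norm <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(txt) == 0L || all(!nzchar(txt))) stop("empty file: ", path)
  txt <- gsub("−", "-", txt)
  utils::read.csv(text = txt, stringsAsFactors = FALSE, ...)
}

#' Read a docking score table
#'
#' Expects a header `molecule_id,<endpoint>,<endpoint>,...` (the packaged
#' `table1_scores.csv` fixture uses endpoints `PS,MS`). Validates
#' uniqueness of ids and that every endpoint cell is numeric and finite.
#'
#' @param path CSV path.
#' @return Data frame with character `molecule_id` and numeric endpoint
#'   columns.
#' @export
read_score_table <- function(path) {
  df <- read_csv_norm(path, colClasses = c(molecule_id = "character"))
  if (!"molecule_id" %in% names(df))
    stop("score table must have a 'molecule_id' column: ", path)
  dup <- unique(df$molecule_id[duplicated(df$molecule_id)])
  if (length(dup))
    stop("duplicated molecule_id(s): ", paste(dup, collapse = ", "))
  eps <- setdiff(names(df), "molecule_id")
  if (length(eps) == 0L) stop("score table has no endpoint columns: ", path)
  for (ep in eps) {
    v <- suppressWarnings(as.numeric(df[[ep]]))
    bad <- which(is.na(v) & !is.na(df[[ep]]) & nzchar(trimws(as.character(df[[ep]]))))
    if (length(bad))
      stop("non-numeric cell(s) in column '", ep, "', row(s) ",
           paste(bad, collapse = ", "))
    df[[ep]] <- v
  }
  df
}

#' Read a derivative prediction table (`table3_predictions.csv` layout)
#'
#' @param path CSV with columns `molecule_id, CM, PM, MM` (relative-error
#'   columns are tolerated and ignored).
#' @return Data frame `molecule_id, CM, PM, MM`.
#' @export
read_predictions <- function(path) {
  df <- read_csv_norm(path, colClasses = c(molecule_id = "character"))
  need <- c("molecule_id", "CM", "PM", "MM")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("prediction table missing column(s): ",
                         paste(miss, collapse = ", "))
  df[need]
}

#' Read an environmental profile table (`table4_env.csv` layout)
#'
#' @param path CSV with columns `molecule_id, cbr_bde_kcal_mol, ec50_mg_l,
#'   log_bcf, vp_pa, insoluble` (0/1 flag for EPI-unmeasurable compounds).
#' @return Data frame of profiles.
#' @export
read_env_profiles <- function(path) {
  df <- read_csv_norm(path, colClasses = c(molecule_id = "character"))
  need <- c("molecule_id", "cbr_bde_kcal_mol", "ec50_mg_l", "log_bcf",
            "vp_pa", "insoluble")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("environmental table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$insoluble <- as.logical(df$insoluble)
  df
}

#' Read a DOE response table (`table6_responses.csv` layout)
#'
#' Empty cells are failed molecular-dynamics runs (`NA`), not zeros.
#'
#' @param path CSV with columns `run`, factor level columns, and one
#'   `<system>_kj_mol` binding-energy column per system.
#' @return List with `design` (run + factor levels) and `responses`
#'   (run + one numeric column per system, names stripped of `_kj_mol`).
#' @export
read_doe_responses <- function(path) {
  df <- read_csv_norm(path)
  if (!"run" %in% names(df)) stop("response table must have a 'run' column")
  sys_cols <- grep("_kj_mol$", names(df), value = TRUE)
  if (length(sys_cols) == 0L) stop("no '*_kj_mol' response columns found")
  fac_cols <- setdiff(names(df), c("run", sys_cols))
  responses <- df[c("run", sys_cols)]
  names(responses) <- c("run", sub("_kj_mol$", "", sys_cols))
  list(design = df[c("run", fac_cols)], responses = responses)
}

#' Read a protein-ligand interaction table (`table7_interactions.csv` layout)
#'
#' @param path CSV with columns `ligand, receptor, residue, distance_A,
#'   bond_type`; one row per listed contact distance.
#' @return Data frame of interaction records.
#' @export
read_interactions <- function(path) {
  df <- read_csv_norm(path, colClasses = "character")
  need <- c("ligand", "receptor", "residue", "distance_A", "bond_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("interaction table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$distance_A <- as.numeric(df$distance_A)
  if (any(!is.finite(df$distance_A) | df$distance_A <= 0))
    stop("contact distances must be positive and finite")
  if (any(!grepl("^[A-Z]{3}\\d+$", df$residue)))
    stop("residue labels must match [A-Z]{3}<number>: ",
         paste(unique(df$residue[!grepl("^[A-Z]{3}\\d+$", df$residue)]),
               collapse = ", "))
  df
}

#' Read an aligned conformer set from per-atom CSV files
#'
#' Each file holds one molecule as rows `element,x,y,z,charge` (coordinates
#' in Angstrom, partial charges in elementary charge units). All files are
#' assumed to share one frame of reference (pre-aligned conformers).
#'
#' @param paths Named character vector of CSV paths; names become molecule
#'   ids (file base names are used when unnamed).
#' @param aligned Logical alignment flag carried on the result.
#' @return A `conformer_set`: named list of atom data frames with attribute
#'   `aligned`.
#' @export
read_conformers <- function(paths, aligned = TRUE) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.csv$", "", basename(paths))
  mols <- lapply(paths, function(p) {
    df <- read_csv_norm(p)
    need <- c("element", "x", "y", "z", "charge")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("atom table ", p, " missing column(s): ",
                           paste(miss, collapse = ", "))
    if (nrow(df) < 1L) stop("atom table ", p, " has no atoms")
    if (any(!is.finite(as.matrix(df[c("x", "y", "z", "charge")]))))
      stop("non-finite coordinate or charge in ", p)
    df[need]
  })
  structure(mols, class = "conformer_set", aligned = aligned)
}
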