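#' Build a conformer set from in-memory atom tables
#'
#' @param molecules Named list of data frames with columns
#'   `element, x, y, z, charge`.
#' @param aligned Logical; the set must be pre-aligned in one common frame
#'   before fields are comparable across molecules.
#' @return A `conformer_set`.
#' @export
conformer_set <- function(molecules, aligned = TRUE) {
  stopifnot(is.list(molecules), length(molecules) >= 1L,
            !is.null(names(molecules)))
  for (nm in names(molecules)) {
    m <- molecules[[nm]]
    stopifnot(all(c("element", "x", "y", "z", "charge") %in% names(m)),
              nrow(m) >= 1L)
    if (any(!is.finite(as.matrix(m[c("x", "y", "z", "charge")]))))
      stop("non-finite coordinate or charge in molecule ", nm)
  }
  structure(molecules, class = "conformer_set", aligned = aligned)
}

# Lennard-Jones well depths (kcal/mol) and vdW radii (Angstrom) per element,
# Tripos-style united values; unknown elements fall back to carbon.
lj_params <- function(element) {
  tab <- list(H  = c(1.50, 0.042), C = c(1.70, 0.107), N = c(1.55, 0.095),
              O  = c(1.52, 0.116), F = c(1.47, 0.109), P = c(1.80, 0.314),
              S  = c(1.80, 0.314), Cl = c(1.75, 0.314), Br = c(1.85, 0.434),
              I  = c(1.98, 0.623))
  out <- t(vapply(element, function(e) {
    p <- tab[[e]]
    if (is.null(p)) tab[["C"]] else p
  }, numeric(2)))
  colnames(out) <- c("radius", "epsilon")
  out
}

#' Default CoMFA probe: sp3 carbon, charge +1
#' @return List with `radius` (A), `epsilon` (kcal/mol), `charge` (e).
#' @export
default_probe <- function() list(radius = 1.70, epsilon = 0.107, charge = 1)

#' Regular lattice enclosing an aligned conformer set
#'
#' @param conformers A `conformer_set`.
#' @param spacing Grid spacing in Angstrom (default 2.0).
#' @param margin Margin beyond the union bounding box in Angstrom
#'   (default 4.0).
#' @return List with `origin`, `spacing`, `dims`, and `points`
#'   (npoints x 3 matrix).
#' @export
field_grid <- function(conformers, spacing = 2.0, margin = 4.0) {
  stopifnot(spacing > 0, margin >= 0)
  xyz <- do.call(rbind, lapply(conformers, function(m)
    as.matrix(m[c("x", "y", "z")])))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  ax <- lapply(1:3, function(i) lo[i] + spacing * (seq_len(dims[i]) - 1L))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  list(origin = lo, spacing = spacing, dims = dims, points = pts)
}

# Steric (LJ 6-12) and electrostatic (Coulomb, distance-dependent
# dielectric eps(r) = r) probe energies of one molecule on a lattice.
probe_energies <- function(mol, points, probe, steric_cutoff) {
  par <- lj_params(mol$element)
  xyz <- as.matrix(mol[c("x", "y", "z")])
  q <- mol$charge
  st <- numeric(nrow(points)); el <- numeric(nrow(points))
  for (a in seq_len(nrow(xyz))) {
    d2 <- (points[, 1] - xyz[a, 1])^2 + (points[, 2] - xyz[a, 2])^2 +
          (points[, 3] - xyz[a, 3])^2
    d2 <- pmax(d2, 1e-12)  # probe exactly on an atom center
    rij <- probe$radius + par[a, "radius"]
    eij <- sqrt(probe$epsilon * par[a, "epsilon"])
    s6 <- (rij * rij / d2)^3
    st <- st + eij * (s6 * s6 - 2 * s6)
    # 332 * q_probe * q_atom / (eps(r) * r) with eps(r) = r  =>  332 q / r^2
    el <- el + 332.0 * probe$charge * q[a] / d2
  }
  list(steric = unname(pmin(pmax(st, -steric_cutoff), steric_cutoff)),
       elec = unname(el),
       excluded = unname(st >= steric_cutoff))
}

#' Compute CoMFA steric/electrostatic lattice fields
#'
#' Places an sp3-carbon, +1 probe at every point of a shared lattice and
#' records the Lennard-Jones 6-12 steric energy (clipped at `+/-
#' steric_cutoff` kcal/mol) and the Coulomb electrostatic energy with a
#' distance-dependent dielectric `eps(r) = r`. Electrostatic values at
#' sterically excluded points (steric at the cutoff) are replaced by the
#' column mean over the non-excluded molecules, the usual CoMFA convention.
#' Lattice columns whose standard deviation over molecules falls below
#' `min_sigma` are dropped (minimum-sigma filter).
#'
#' @param conformers A `conformer_set` (must be aligned).
#' @param probe Probe parameters, see [default_probe()].
#' @param spacing,margin Lattice geometry in Angstrom.
#' @param steric_cutoff Truncation in kcal/mol (default 30).
#' @param min_sigma Minimum column standard deviation in kcal/mol
#'   (default 2).
#' @param grid Optional pre-built lattice from [field_grid()]; required when
#'   computing fields for prediction so new molecules land on the training
#'   lattice.
#' @param columns Optional column metadata of a fitted model; when given the
#'   variance filter is skipped and exactly those columns are produced.
#' @return List of class `qsar_fields`: `X` (molecules x retained columns),
#'   `meta` (data frame: `field`, `point` index), `grid`.
#' @export
compute_fields <- function(conformers, probe = default_probe(),
                           spacing = 2.0, margin = 4.0,
                           steric_cutoff = 30, min_sigma = 2.0,
                           grid = NULL, columns = NULL) {
  if (!isTRUE(attr(conformers, "aligned")))
    stop("conformers are not flagged as aligned; fields are not comparable")
  if (all(vapply(conformers, function(m) all(m$charge == 0), logical(1))))
    warning("all partial charges are zero; electrostatic block will be zero")
  if (is.null(grid)) grid <- field_grid(conformers, spacing, margin)
  np <- nrow(grid$points)
  nm <- length(conformers)
  ster <- matrix(0, nm, np); elec <- matrix(0, nm, np); excl <- matrix(FALSE, nm, np)
  for (i in seq_len(nm)) {
    e <- probe_energies(conformers[[i]], grid$points, probe, steric_cutoff)
    ster[i, ] <- e$steric; elec[i, ] <- e$elec; excl[i, ] <- e$excluded
  }
  # column-mean replacement of electrostatics inside the steric envelope
  for (j in which(colSums(excl) > 0)) {
    ok <- !excl[, j]
    elec[!ok, j] <- if (any(ok)) mean(elec[ok, j]) else 0
  }
  X <- cbind(ster, elec)
  meta <- data.frame(field = rep(c("steric", "electrostatic"), each = np),
                     point = rep(seq_len(np), 2L))
  keep <- if (is.null(columns)) {
    # minimum-sigma filter applies at training time only
    apply(X, 2, stats::sd) >= min_sigma
  } else {
    # prediction time: reproduce the training model's retained columns
    match(paste(columns$field, columns$point),
          paste(meta$field, meta$point))
  }
  X <- X[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  rownames(X) <- names(conformers)
  colnames(X) <- paste0(substr(meta$field, 1, 1), meta$point)
  structure(list(X = X, meta = meta, grid = grid), class = "qsar_fields")
}

#' Assemble a QSAR dataset from fields and an activity vector
#'
#' @param fields A `qsar_fields` object (or any list with `X` and `meta`).
#' @param activity Named numeric vector (names = molecule ids) or numeric
#'   vector in row order of `fields$X`; typically the composite synergy
#'   score CS, or PS/MS for the single-factor models.
#' @return List of class `qsar_dataset`: `X`, `y`, `meta`.
#' @export
qsar_dataset <- function(fields, activity) {
  X <- fields$X
  if (!is.null(names(activity))) {
    miss <- setdiff(rownames(X), names(activity))
    if (length(miss)) stop("activity missing for: ", paste(miss, collapse = ", "))
    activity <- activity[rownames(X)]
  }
  if (length(activity) != nrow(X))
    stop("activity length ", length(activity), " != ", nrow(X), " molecules")
  if (any(!is.finite(activity))) stop("non-finite activity values")
  structure(list(X = X, y = as.numeric(activity), meta = fields$meta),
            class = "qsar_dataset")
}
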