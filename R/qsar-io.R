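#' Serialize a fitted PLS model to JSON
#'
#' Stores coefficients, centering vectors, fit statistics, column metadata
#' and (when supplied) the lattice geometry and probe, so the model can be
#' reloaded and applied to new aligned structures.
#'
#' @param model A `pls_model` from [fit_pls_loo()].
#' @param path Output JSON path.
#' @param grid Optional lattice (from the `qsar_fields` used to train).
#' @param probe Optional probe parameters.
#' @param steric_cutoff,min_sigma Field-generation settings to reproduce at
#'   prediction time.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path, grid = NULL, probe = NULL,
                            steric_cutoff = 30, min_sigma = 2.0) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(
    coefficients = unname(model$coefficients),
    xbar = unname(model$xbar), ybar = model$ybar,
    ncomp = model$ncomp, q2 = model$q2, r2 = model$r2,
    see = model$see, fstat = model$fstat,
    ybar_train = model$ybar_train, n_train = model$n_train,
    col_sd = unname(model$col_sd),
    meta = model$meta,
    steric_cutoff = steric_cutoff, min_sigma = min_sigma)
  if (!is.null(grid))
    obj$grid <- list(origin = unname(grid$origin), spacing = grid$spacing,
                     dims = unname(grid$dims))
  if (!is.null(probe)) obj$probe <- probe
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load a serialized PLS model
#'
#' @param path JSON path written by [write_pls_model()].
#' @return A `pls_model` with extra elements `grid`, `probe`,
#'   `steric_cutoff`, `min_sigma` when they were stored.
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$grid)) {
    ax <- lapply(1:3, function(i)
      obj$grid$origin[i] + obj$grid$spacing * (seq_len(obj$grid$dims[i]) - 1L))
    obj$grid$points <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]],
                                             z = ax[[3]],
                                             KEEP.OUT.ATTRS = FALSE))
  }
  structure(obj, class = "pls_model")
}

#' Predict activities for new aligned structures with a stored model
#'
#' Recomputes the steric/electrostatic fields of the new conformers on the
#' model's training lattice, restricted to the model's retained columns,
#' then applies the PLS coefficients.
#'
#' @param model A `pls_model` carrying `grid` and `probe`
#'   ([read_pls_model()] of a model written with them).
#' @param conformers A `conformer_set` aligned to the training frame.
#' @return Named numeric predictions.
#' @export
predict_structures <- function(model, conformers) {
  if (is.null(model$grid)) stop("model was stored without its lattice")
  probe <- if (is.null(model$probe)) default_probe() else model$probe
  f <- compute_fields(conformers, probe = probe,
                      steric_cutoff = model$steric_cutoff %||% 30,
                      grid = model$grid, columns = model$meta)
  stats::setNames(predict(model, f$X), names(conformers))
}
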