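# Seeded generators emulating the statistical structure of each pipeline
# input, so every stage is testable offline with known ground truth.

# Sample moments of the packaged docking-score table; used as generator
# defaults so simulated cohorts live on the scale of the real one
# (PS/MS means ~47/52, sds ~8.5/6.9, correlation ~0.42, range ~22-67).
table1_moments <- function() {
  tab <- read_score_table(synergy_fixture("table1_scores.csv"))
  list(mean = c(PS = mean(tab$PS), MS = mean(tab$MS)),
       sd = c(PS = stats::sd(tab$PS), MS = stats::sd(tab$MS)),
       rho = stats::cor(tab$PS, tab$MS))
}

#' Simulate a docking score table
#'
#' Draws (PS, MS) pairs from a bivariate normal with the requested moments
#' (defaults: the sample moments of the packaged worked table), clipped to
#' stay positive, one molecule per row. Deterministic under `seed`.
#'
#' @param n Number of molecules (>= 2).
#' @param mean,sd Length-2 numeric vectors (endpoint order PS, MS).
#' @param rho Inter-endpoint correlation in \[-1, 1\].
#' @param seed Integer seed.
#' @return Data frame `molecule_id, PS, MS`.
#' @export
gen_score_table <- function(n = 177L, mean = NULL, sd = NULL, rho = NULL,
                            seed = 1L) {
  if (n < 2L) stop("need n >= 2")
  mom <- if (is.null(mean) || is.null(sd) || is.null(rho)) table1_moments()
  if (is.null(mean)) mean <- mom$mean
  if (is.null(sd)) sd <- mom$sd
  if (is.null(rho)) rho <- mom$rho
  stopifnot(length(mean) == 2L, length(sd) == 2L, all(sd > 0), abs(rho) <= 1)
  set.seed(seed)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  ps <- mean[1] + sd[1] * z1
  ms <- mean[2] + sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  data.frame(molecule_id = as.character(seq_len(n)),
             PS = pmax(ps, 0.1), MS = pmax(ms, 0.1))
}

#' Simulate a QSAR dataset with planted latent structure
#'
#' `X = scores %*% loadings + noise`, `y` linear in the latent scores, with
#' columns labeled steric/electrostatic and the coefficient mass split
#' between the two blocks set by `mass_split`. The returned truth object
#' carries the latent scores, the true coefficient vector and the noise-free
#' activity, enabling parameter-recovery tests.
#'
#' @param n_molecules Number of rows (default 40).
#' @param n_components Planted latent components (default 3).
#' @param n_steric,n_electrostatic Columns per field block (default 30/30).
#' @param mass_split Target steric:electrostatic share of the
#'   `|coefficient| * column-sd` mass, length-2 and positive
#'   (default `c(1, 3)`, i.e. 25%/75%).
#' @param noise_sd Activity noise as a fraction of the noise-free activity
#'   standard deviation (default 0.1).
#' @param x_noise_sd Descriptor noise standard deviation (default 0.05).
#' @param seed Integer seed.
#' @return A `qsar_dataset` with extra element `truth`.
#' @export
gen_field_dataset <- function(n_molecules = 40L, n_components = 3L,
                              n_steric = 30L, n_electrostatic = 30L,
                              mass_split = c(1, 3), noise_sd = 0.1,
                              x_noise_sd = 0.05, seed = 1L) {
  if (n_components > n_molecules - 2L)
    stop("need n_components <= n_molecules - 2")
  stopifnot(length(mass_split) == 2L, all(mass_split > 0), noise_sd >= 0)
  set.seed(seed)
  p <- n_steric + n_electrostatic
  scores <- matrix(stats::rnorm(n_molecules * n_components), n_molecules)
  loadings <- matrix(stats::rnorm(n_components * p), n_components)
  # scale each block's loadings so the coefficient mass lands on mass_split
  blk <- rep(c("steric", "electrostatic"), c(n_steric, n_electrostatic))
  w <- mass_split / c(n_steric, n_electrostatic)
  loadings <- sweep(loadings, 2, ifelse(blk == "steric", w[1], w[2]), `*`)
  X <- scores %*% loadings +
    matrix(stats::rnorm(n_molecules * p, sd = x_noise_sd), n_molecules)
  beta <- stats::rnorm(n_components)
  y0 <- drop(scores %*% beta)
  y <- y0 + stats::rnorm(n_molecules, sd = noise_sd * stats::sd(y0))
  rownames(X) <- as.character(seq_len(n_molecules))
  colnames(X) <- paste0(substr(blk, 1, 1), seq_len(p))
  meta <- data.frame(field = blk, point = seq_len(p))
  structure(list(X = X, y = y, meta = meta,
                 truth = list(scores = scores, loadings = loadings,
                              beta = beta, y_noiseless = y0)),
            class = "qsar_dataset")
}

#' Simulate DOE binding-energy responses with known main effects
#'
#' `energy = control + sum(effects * level) + noise` per run, clipped to
#' stay nonpositive (a bound complex); negative effects strengthen binding.
#' The returned table follows the `run, <system>` layout consumed by
#' [scheme_improvements()] and [factor_effects()].
#'
#' @param design 0/1 design matrix (runs x factors).
#' @param effects Named per-factor main effects in kJ/mol (negative =
#'   stronger binding on addition); names must match design columns.
#' @param control Control binding energy in kJ/mol (default -40, the scale
#'   of the plant system's blank run).
#' @param noise_sd Response noise standard deviation in kJ/mol.
#' @param system Response column name (default `"plant"`).
#' @param seed Integer seed.
#' @return Data frame `run, <system>` including a control run `0`.
#' @export
gen_doe_responses <- function(design, effects, control = -40,
                              noise_sd = 1, system = "plant", seed = 1L) {
  design <- as.matrix(design)
  if (is.null(names(effects)) || !setequal(names(effects), colnames(design)))
    stop("effects must be named after the design columns")
  ids <- rownames(design)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(design)))
  ids <- sub("^run", "", ids)
  set.seed(seed)
  noise <- stats::rnorm(nrow(design) + 1L, sd = noise_sd)
  e <- control + drop(design %*% effects[colnames(design)]) +
    noise[seq_len(nrow(design))]
  if (!"0" %in% ids) {  # L12-style designs have no built-in blank run
    ids <- c("0", ids)
    e <- c(control + noise[length(noise)], e)
  }
  if (any(e > 0)) {
    warning(sum(e > 0), " run(s) pushed above zero; clipped to 0 (unbound)")
    e <- pmin(e, 0)
  }
  out <- data.frame(run = ids, energy = e)
  names(out)[2] <- system
  out
}
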