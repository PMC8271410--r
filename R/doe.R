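#' Taguchi L12 orthogonal array
#'
#' The standard 12-run Plackett-Burman two-level array. Each column is
#' balanced (six 1s, six 0s) and every pair of columns shows each of the
#' four level combinations exactly three times. Levels are coded 1 =
#' addition of the regulatory factor, 0 = no addition.
#'
#' @param n_factors Number of factors, at most 11 (default 11).
#' @param labels Optional factor labels; default `LETTERS[1:n_factors]`,
#'   matching the study's A = carbon dioxide ... K = hydrogen sulfide
#'   assignment.
#' @return Integer matrix 12 x n_factors of 0/1 levels, rows named
#'   `run1..run12`.
#' @export
taguchi_L12 <- function(n_factors = 11L, labels = NULL) {
  if (n_factors < 1L || n_factors > 11L)
    stop("L12 supports 1..11 factors, got ", n_factors)
  # Plackett-Burman generator row for N = 12, cycled; 12th run all-low.
  gen <- c(1, 1, 0, 1, 1, 1, 0, 0, 0, 1, 0)
  m <- matrix(0L, 12L, 11L)
  for (i in 1:11) m[i, ] <- as.integer(gen[((seq_len(11) + i - 2) %% 11) + 1])
  m <- m[, seq_len(n_factors), drop = FALSE]
  if (is.null(labels)) labels <- LETTERS[seq_len(n_factors)]
  dimnames(m) <- list(paste0("run", 1:12), labels)
  m
}

#' Two-level full factorial design
#'
#' All `2^k` level combinations in lexicographic order with the all-zero
#' (blank control) combination first, run ids `0 .. 2^k - 1`.
#'
#' @param factors Factor labels (character) or a count `k`.
#' @return Integer matrix `2^k x k` of 0/1 levels, rownames = run ids.
#' @export
full_factorial <- function(factors = 4L) {
  if (is.numeric(factors)) factors <- LETTERS[seq_len(factors)]
  k <- length(factors)
  if (k < 1L) stop("need at least one factor")
  ids <- 0:(2^k - 1)
  m <- t(matrix(vapply(ids, function(r) as.integer(intToBits(r))[k:1],
                       integer(k)), nrow = k))
  dimnames(m) <- list(as.character(0:(2^k - 1)), factors)
  m
}

#' Larger-the-better Taguchi signal-to-noise ratio
#'
#' `SNR = -10 log10(mean(1 / y^2))` in dB. Responses must be positive
#' magnitudes; for binding energies pass `abs(energy)`, since stronger
#' (more negative) binding is the desired outcome.
#'
#' @param y Positive response magnitudes of one run (replicates allowed).
#' @return SNR in dB.
#' @export
snr_larger_is_better <- function(y) {
  if (length(y) < 1L || any(!is.finite(y)) || any(y <= 0))
    stop("larger-the-better SNR requires positive finite responses")
  -10 * log10(mean(1 / y^2))
}

#' Factor effects from per-run SNR values
#'
#' For each design column, the mean SNR over runs at level 1 and level 0,
#' their absolute difference (delta), and the delta rank (1 = most
#' influential; ties keep input order).
#'
#' @param design 0/1 design matrix (runs x factors), e.g. [taguchi_L12()].
#' @param snr One finite SNR per run.
#' @return Data frame `factor, snr_level1, snr_level0, delta, rank`.
#' @export
factor_effects <- function(design, snr) {
  design <- as.matrix(design)
  if (length(snr) != nrow(design))
    stop("need one SNR per run: ", nrow(design), " runs vs ",
         length(snr), " SNR values (missing runs are not allowed)")
  if (any(!is.finite(snr))) stop("non-finite SNR values")
  eff <- data.frame(
    factor = colnames(design),
    snr_level1 = apply(design, 2, function(l) mean(snr[l == 1])),
    snr_level0 = apply(design, 2, function(l) mean(snr[l == 0])),
    stringsAsFactors = FALSE)
  eff$delta <- abs(eff$snr_level1 - eff$snr_level0)
  eff$rank <- rank(-eff$delta, ties.method = "first")
  rownames(eff) <- NULL
  eff
}

#' Divergence factors common to two systems
#'
#' Intersects the top-k most influential factors (by delta rank) of two
#' effect ledgers, e.g. the plant and microbial screens; the shared factors
#' are candidates for the follow-up full factorial.
#'
#' @param ledger_a,ledger_b Data frames with `factor` and `rank` columns
#'   ([factor_effects()] output, or the printed ledger with its ranks).
#' @param top_k How many leading factors to take from each (default 6).
#' @return Data frame `factor, rank_a, rank_b` for the intersection, ordered
#'   by `rank_a`.
#' @export
common_divergence_factors <- function(ledger_a, ledger_b, top_k = 6L) {
  top <- function(l) l$factor[l$rank <= top_k]
  shared <- intersect(top(ledger_a), top(ledger_b))
  out <- data.frame(factor = shared,
                    rank_a = ledger_a$rank[match(shared, ledger_a$factor)],
                    rank_b = ledger_b$rank[match(shared, ledger_b$factor)])
  out[order(out$rank_a), , drop = FALSE]
}

#' Evaluate regulatory schemes by binding-energy improvement
#'
#' Relative improvement of each run over the blank control, per system:
#' `(|E_run| - |E_control|) / |E_control| * 100` (positive = stronger
#' binding, i.e. the sign convention of every printed percentage). A run is
#' synergy-flagged when both systems completed and both improved; its
#' synergy average is the arithmetic mean of the two improvements, and the
#' best scheme maximizes that average among flagged runs. Runs missing one
#' system are marked `incomplete` and excluded from the synergy ranking.
#'
#' @param responses Data frame `run, <system1>, <system2>, ...` of binding
#'   energies in kJ/mol (`NA` = failed run), including a control run.
#' @param control Run id of the blank control (default `0`).
#' @return List of class `scheme_evaluation`: `table` (per-run improvements,
#'   synergy flag/average), `best` (run id or `NA`), `control` (energies).
#' @export
scheme_improvements <- function(responses, control = 0) {
  stopifnot(is.data.frame(responses), "run" %in% names(responses))
  systems <- setdiff(names(responses), "run")
  if (length(systems) < 1L) stop("no system response columns")
  ctl_row <- responses$run == control
  if (sum(ctl_row) != 1L) stop("control run ", control, " not found (or duplicated)")
  ectl <- unlist(responses[ctl_row, systems, drop = FALSE])
  if (any(is.na(ectl) | ectl == 0))
    stop("control binding energy missing or zero for: ",
         paste(systems[is.na(ectl) | ectl == 0], collapse = ", "))
  runs <- responses[!ctl_row, , drop = FALSE]
  imp <- sapply(systems, function(s)
    (abs(runs[[s]]) - abs(ectl[[s]])) / abs(ectl[[s]]) * 100)
  imp <- matrix(imp, nrow = nrow(runs),
                dimnames = list(NULL, paste0("improvement_", systems)))
  complete <- rowSums(is.na(imp)) == 0
  synergy <- complete & apply(imp > 0, 1, all)
  synergy[is.na(synergy)] <- FALSE
  avg <- ifelse(synergy, rowMeans(imp), NA_real_)
  tab <- data.frame(run = runs$run, imp, incomplete = !complete,
                    synergy = synergy, synergy_average = avg)
  best <- if (any(synergy)) tab$run[which.max(avg)] else NA
  structure(list(table = tab, best = best, control = ectl),
            class = "scheme_evaluation")
}

#' @export
print.scheme_evaluation <- function(x, ...) {
  cat("Regulatory scheme evaluation over", nrow(x$table), "runs\n")
  fl <- x$table[x$table$synergy, , drop = FALSE]
  if (nrow(fl)) {
    cat("Synergy-flagged runs (both systems improved):\n")
    for (i in seq_len(nrow(fl)))
      cat(sprintf("  run %-3s synergy average %8.2f%%\n",
                  fl$run[i], fl$synergy_average[i]))
    cat("Best scheme: run", x$best, "\n")
  } else cat("No run improved both systems.\n")
  invisible(x)
}
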