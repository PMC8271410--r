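#' Rank-based single score for one molecule
#'
#' Maps a rank within a cohort onto a 0-100 queuing score: the first place
#' (rank 1, strongest binder) scores 100, the last place scores 0, and
#' intermediate (possibly fractional, tied) ranks are linearly interpolated,
#' `SS = (n - k) / (n - 1) * 100`.
#'
#' @param k Rank (1 = best). May be fractional under average-tie ranking.
#' @param n Cohort size (number of successfully docked molecules), `n >= 2`.
#' @return Numeric vector of scores in \[0, 100\].
#' @examples
#' single_score(1, 177)    # 100
#' single_score(177, 177)  # 0
#' @export
single_score <- function(k, n) {
  if (length(n) != 1L || !is.finite(n) || n < 2)
    stop("cohort size n must be a single value >= 2, got ", deparse(n))
  if (any(!is.finite(k)) || any(k < 1) || any(k > n))
    stop("rank k must lie in [1, n]; offending value(s): ",
         paste(k[!is.finite(k) | k < 1 | k > n], collapse = ", "))
  (n - k) / (n - 1) * 100
}

#' Rank scores in descending order of merit
#'
#' A larger docking score means stronger binding, hence a smaller (better)
#' rank. Ties are resolved by `tie_policy`; the default fractional "average"
#' ranks make the result invariant under permutation of tied inputs.
#'
#' @param values Finite numeric vector of docking scores.
#' @param tie_policy One of `"average"` (default), `"min"`, `"ordinal"`.
#' @param ids Optional identifiers used in error messages for non-finite
#'   entries.
#' @return Numeric rank vector, 1 = best.
#' @export
rank_descending <- function(values, tie_policy = c("average", "min", "ordinal"),
                            ids = NULL) {
  tie_policy <- match.arg(tie_policy)
  bad <- !is.finite(values)
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad) else ids[bad]
    stop("non-finite scores for: ", paste(lab, collapse = ", "))
  }
  rank(-values, ties.method = switch(tie_policy,
                                     average = "average",
                                     min     = "min",
                                     ordinal = "first"))
}

#' Composite synergy score (CS) from per-endpoint docking scores
#'
#' Implements the queuing scoring method: each endpoint column (e.g. the
#' plant-enzyme score PS and the microbial-enzyme score MS) is ranked over
#' the cohort, converted to a 0-100 single score via [single_score()], and
#' the per-molecule composite `CS = sum(SS_j * W_j) / sum(W_j)` is taken over
#' the endpoints. Under the default `weight_mode = "own_docking_scores"` the
#' weight `W_j` is that molecule's own docking score for endpoint j, so a
#' molecule binding one enzyme much more strongly pulls its CS toward that
#' endpoint's single score.
#'
#' @param table Data frame with a `molecule_id` column plus one numeric
#'   column per endpoint (see [read_score_table()]).
#' @param weight_mode `"own_docking_scores"` (default) or `"fixed"`.
#' @param weights Named numeric vector of per-endpoint weights, required for
#'   `weight_mode = "fixed"`; must be strictly positive.
#' @param endpoints Character vector naming the endpoint columns; defaults to
#'   every column except `molecule_id`.
#' @param tie_policy Passed to [rank_descending()].
#' @return A data frame with columns `molecule_id`, the raw endpoint scores,
#'   `SS_<endpoint>` single scores, and `CS`; attribute `n` holds the cohort
#'   size used.
#' @export
composite_scores <- function(table,
                             weight_mode = c("own_docking_scores", "fixed"),
                             weights = NULL,
                             endpoints = NULL,
                             tie_policy = "average") {
  weight_mode <- match.arg(weight_mode)
  stopifnot(is.data.frame(table), "molecule_id" %in% names(table))
  if (is.null(endpoints))
    endpoints <- setdiff(names(table), "molecule_id")
  if (length(endpoints) < 1L) stop("no endpoint columns found")
  missing_cols <- setdiff(endpoints, names(table))
  if (length(missing_cols))
    stop("missing endpoint column(s): ", paste(missing_cols, collapse = ", "))

  # molecules lacking any endpoint are dropped, shrinking the cohort n
  complete <- stats::complete.cases(table[endpoints])
  if (!all(complete)) {
    warning("excluding ", sum(!complete), " molecule(s) with missing endpoint scores: ",
            paste(table$molecule_id[!complete], collapse = ", "))
    table <- table[complete, , drop = FALSE]
  }
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 fully scored molecules, got ", n)

  ss <- sapply(endpoints, function(ep) {
    k <- rank_descending(table[[ep]], tie_policy, ids = table$molecule_id)
    single_score(k, n)
  })
  ss <- matrix(ss, nrow = n, dimnames = list(NULL, paste0("SS_", endpoints)))

  if (weight_mode == "own_docking_scores") {
    w <- as.matrix(table[endpoints])
  } else {
    if (is.null(weights) || !all(endpoints %in% names(weights)))
      stop("weight_mode = 'fixed' requires a named weight per endpoint")
    w <- matrix(rep(weights[endpoints], each = n), nrow = n)
  }
  if (any(w <= 0))
    stop("nonpositive weight for molecule(s): ",
         paste(unique(table$molecule_id[rowSums(w <= 0) > 0]), collapse = ", "))

  cs <- rowSums(ss * w) / rowSums(w)
  out <- cbind(table[c("molecule_id", endpoints)], ss, CS = cs)
  rownames(out) <- NULL
  attr(out, "n") <- n
  out
}
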