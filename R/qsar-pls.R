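# NIPALS PLS1 on mean-centered data (CoMFA convention: no autoscaling).
# Returns per-component weights/loadings and the regression coefficients for
# every component count up to ncomp, so LOO can reuse one decomposition.
pls_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar); f <- y - ybar
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); qv <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break  # residual exhausted
    w <- w / wn
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - t %*% t(pvec)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pvec; qv[a] <- qa
    used <- a
  }
  if (used == 0L) stop("PLS found no usable component (constant X or y)")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  qv <- qv[seq_len(used)]
  # B_a = W_a (P_a' W_a)^-1 q_a for each component count a
  coefs <- matrix(0, p, used)
  for (a in seq_len(used)) {
    Wa <- W[, 1:a, drop = FALSE]; Pa <- P[, 1:a, drop = FALSE]
    coefs[, a] <- Wa %*% solve(crossprod(Pa, Wa), qv[1:a])
  }
  list(coefs = coefs, xbar = xbar, ybar = ybar, ncomp = used)
}

pls_predict_raw <- function(fit, X, a) {
  b <- fit$coefs[, a]
  drop(sweep(as.matrix(X), 2, fit$xbar) %*% b) + fit$ybar
}

#' Fit a PLS model with leave-one-out component selection
#'
#' For each candidate component count the model is refit with one training
#' molecule left out at a time; `q2 = 1 - PRESS / SS_total` summarizes the
#' LOO predictions against the training mean. The component count maximizing
#' q2 (smallest count on ties) is retained, the final model is refit on the
#' full training set, and the usual internal statistics are reported:
#' `R2 = 1 - RSS/SS_total`, `SEE = sqrt(RSS / (N - n - 1))`,
#' `F = (R2/n) / ((1 - R2)/(N - n - 1))`.
#'
#' @param dataset A `qsar_dataset` (see [qsar_dataset()]), or a list with
#'   `X`, `y` and optionally `meta`.
#' @param max_components Cap on components; defaults to
#'   `min(ntrain - 1, 10)`.
#' @param train Optional logical/integer index of training molecules
#'   (default: all).
#' @return Object of class `pls_model`: coefficients at the optimal count,
#'   `q2`, `q2_by_ncomp`, `ncomp`, `r2`, `see`, `fstat`, `ybar_train`, plus
#'   the column metadata for field-fraction reporting.
#' @export
fit_pls_loo <- function(dataset, max_components = NULL, train = NULL) {
  X <- as.matrix(dataset$X); y <- dataset$y
  if (is.null(train)) train <- seq_len(nrow(X))
  Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
  N <- nrow(Xtr)
  if (N < 5L) stop("training set must have at least 5 molecules, got ", N)
  if (stats::sd(ytr) == 0) stop("constant activity: SS_total is zero")
  if (is.null(max_components)) max_components <- min(N - 1L, 10L)
  if (max_components > N - 1L)
    stop("max_components must be <= training size - 1")

  amax <- min(max_components, N - 1L, ncol(Xtr))
  press <- matrix(NA_real_, N, amax)
  for (i in seq_len(N)) {
    fit_i <- pls_nipals(Xtr[-i, , drop = FALSE], ytr[-i], amax)
    for (a in seq_len(amax))
      press[i, a] <- (ytr[i] - pls_predict_raw(
        fit_i, Xtr[i, , drop = FALSE], min(a, fit_i$ncomp)))^2
  }
  ss_tot <- sum((ytr - mean(ytr))^2)
  q2s <- 1 - colSums(press) / ss_tot
  nopt <- which.max(q2s)  # first index on ties = smaller count

  fit <- pls_nipals(Xtr, ytr, amax)
  a <- min(nopt, fit$ncomp)
  resid <- ytr - pls_predict_raw(fit, Xtr, a)
  rss <- sum(resid^2)
  r2 <- 1 - rss / ss_tot
  dfree <- N - a - 1L
  see <- if (dfree > 0) sqrt(rss / dfree) else NA_real_
  fstat <- if (dfree > 0 && r2 < 1) (r2 / a) / ((1 - r2) / dfree) else Inf

  structure(list(coefficients = fit$coefs[, a], xbar = fit$xbar,
                 ybar = fit$ybar, ncomp = a, q2 = q2s[nopt],
                 q2_by_ncomp = q2s, r2 = r2, see = see, fstat = fstat,
                 ybar_train = mean(ytr), n_train = N,
                 col_sd = apply(Xtr, 2, stats::sd),
                 meta = dataset$meta), class = "pls_model")
}

#' Predict activities from a fitted PLS model
#' @param object A `pls_model`.
#' @param newdata Matrix (or `qsar_dataset`) with the model's columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else newdata
  drop(sweep(as.matrix(X), 2, object$xbar) %*% object$coefficients) +
    object$ybar
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS model:", x$ncomp, "component(s) over", length(x$coefficients),
      "lattice columns\n")
  cat(sprintf("  q2 (LOO) = %.3f   R2 = %.3f   SEE = %.4g   F = %.4g\n",
              x$q2, x$r2, x$see, x$fstat))
  ff <- try(field_fractions(x), silent = TRUE)
  if (!inherits(ff, "try-error"))
    cat(sprintf("  field fractions: steric %.2f%%, electrostatic %.2f%%\n",
                ff["steric"], ff["electrostatic"]))
  invisible(x)
}

#' External predictive coefficient r2pred
#'
#' `r2pred = 1 - sum((y - yhat)^2) / sum((y - ybar_train)^2)`, the external
#' analog of q2: test residuals referenced to the training-set mean.
#'
#' @param y_test Experimental activities of the test molecules.
#' @param y_pred Model predictions for the same molecules.
#' @param ybar_train Mean activity of the training set.
#' @return The scalar r2pred (at most 1; 1 iff all residuals vanish).
#' @export
r2_pred <- function(y_test, y_pred, ybar_train) {
  stopifnot(length(y_test) == length(y_pred), length(y_test) >= 1L,
            is.finite(ybar_train))
  denom <- sum((y_test - ybar_train)^2)
  if (denom == 0)
    stop("all test activities equal the training mean: r2pred undefined")
  1 - sum((y_test - y_pred)^2) / denom
}

#' Model-quality ledger
#'
#' Applies the study's reliability rules: the model is generally reliable
#' when `q2 > 0.5`; there is no over-fitting when `(R2 - q2)/R2 < 25%`;
#' external predictivity requires `r2pred > 0.6`.
#'
#' @param model A `pls_model` (or a list with `q2`, `r2`).
#' @param r2pred Optional external validation coefficient.
#' @return Data frame with one row per criterion: `criterion`, `value`,
#'   `threshold`, `pass`.
#' @export
quality_report <- function(model, r2pred = NULL) {
  overfit <- (model$r2 - model$q2) / model$r2 * 100
  out <- data.frame(
    criterion = c("q2_reliability", "overfit_gap_pct"),
    value = c(model$q2, overfit),
    threshold = c(0.5, 25),
    pass = c(model$q2 > 0.5, overfit < 25),
    stringsAsFactors = FALSE)
  if (!is.null(r2pred))
    out <- rbind(out, data.frame(criterion = "r2pred", value = r2pred,
                                 threshold = 0.6, pass = r2pred > 0.6))
  out
}

#' Steric/electrostatic field contributions of a fitted model
#'
#' Contribution of each field type as the percentage of the total
#' `|coefficient| * column-sd` mass, the quantity SYBYL prints as field
#' fractions.
#'
#' @param model A `pls_model` fitted on a dataset with column metadata.
#' @return Named numeric vector `c(steric = , electrostatic = )`, summing
#'   to 100.
#' @export
field_fractions <- function(model) {
  if (is.null(model$meta)) stop("model carries no column metadata")
  mass <- abs(model$coefficients) * model$col_sd
  tot <- tapply(mass, factor(model$meta$field,
                             levels = c("steric", "electrostatic")), sum)
  tot[is.na(tot)] <- 0
  if (sum(tot) == 0) return(c(steric = 0, electrostatic = 0))
  out <- 100 * tot / sum(tot)
  c(steric = unname(out["steric"]), electrostatic = unname(out["electrostatic"]))
}

#' Stratified 3:1 train/test split
#'
#' Deterministic under `seed`; molecules are stratified on activity
#' quartiles so both sets span the activity range, then split about 3:1
#' within each stratum.
#'
#' @param y Activity vector (length >= 8).
#' @param ratio Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` = training member.
#' @export
split_train_test <- function(y, ratio = 0.75, seed = 1L) {
  n <- length(y)
  if (n < 8L) stop("need at least 8 molecules to split, got ", n)
  qs <- stats::quantile(y, c(.25, .5, .75), type = 7)
  stratum <- findInterval(y, qs, rightmost.closed = FALSE) + 1L
  train <- logical(n)
  target <- round(ratio * n)
  strata <- split(seq_len(n), stratum)
  sizes <- lengths(strata)
  ntr <- pmax(1L, pmin(sizes - 1L, floor(ratio * sizes)))
  # hand the rounding remainder to the strata with the largest fractional
  # part so the global count hits round(ratio * n)
  short <- target - sum(ntr)
  if (short > 0) {
    frac <- ratio * sizes - floor(ratio * sizes)
    for (s in order(-frac)[seq_len(min(short, length(strata)))])
      if (ntr[s] < sizes[s] - 1L) ntr[s] <- ntr[s] + 1L
  }
  set.seed(seed)
  for (s in seq_along(strata))
    train[sample(strata[[s]], ntr[s])] <- TRUE
  train
}
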