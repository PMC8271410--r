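# Shared builders for in-code fixtures and independent oracles.

fixture <- function(name) synergy_fixture(name)

toy_score_table <- function(ps, ms, ids = as.character(seq_along(ps))) {
  data.frame(molecule_id = ids, PS = ps, MS = ms)
}

# Independent composite-score oracle: per-molecule loop, no vectorization,
# ranks recomputed by counting larger values (average ties).
cs_bruteforce <- function(ps, ms) {
  n <- length(ps)
  rank_of <- function(v, i) sum(v > v[i]) + (1 + sum(v == v[i])) / 2
  ss <- function(k) (n - k) / (n - 1) * 100
  vapply(seq_len(n), function(i) {
    ssp <- ss(rank_of(ps, i)); ssm <- ss(rank_of(ms, i))
    (ssp * ps[i] + ssm * ms[i]) / (ps[i] + ms[i])
  }, numeric(1))
}

# Independent PLS1 oracle via the Krylov-subspace (Helland) formulation:
# with centered X, C = X'X and s = X'y, the a-component PLS coefficient is
# the least-squares solution restricted to span{s, Cs, ..., C^(a-1) s}.
pls_krylov_coef <- function(X, y, a) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  C <- crossprod(Xc)
  K <- matrix(0, ncol(X), a)
  v <- s
  for (j in seq_len(a)) {
    K[, j] <- v / sqrt(sum(v^2))
    v <- C %*% K[, j]
  }
  K <- qr.Q(qr(K))  # orthonormal basis for numerical sanity
  drop(K %*% solve(crossprod(K, C %*% K), crossprod(K, s)))
}

pls_krylov_predict <- function(Xtr, ytr, Xnew, a) {
  b <- pls_krylov_coef(Xtr, ytr, a)
  drop(sweep(as.matrix(Xnew), 2, colMeans(as.matrix(Xtr))) %*% b) + mean(ytr)
}

# Two tiny rigid "molecules": a 3-atom bromobenzene-ish fragment and a
# 4-atom variant, sharing one frame (pre-aligned by construction).
toy_conformers <- function() {
  m1 <- data.frame(element = c("C", "C", "Br"),
                   x = c(0, 1.4, 2.8), y = c(0, 0, 0.5), z = 0,
                   charge = c(-0.1, 0.15, -0.05))
  m2 <- data.frame(element = c("C", "C", "O", "H"),
                   x = c(0, 1.4, 2.4, 3.0), y = c(0, 0.2, -0.4, 0.4), z = 0,
                   charge = c(-0.12, 0.2, -0.3, 0.22))
  conformer_set(list(a = m1, b = m2))
}

# A randomized conformer cohort big enough to fit PLS on real lattice
# fields: n rigid 3-atom fragments jittered around a template.
random_conformers <- function(n, seed = 1) {
  set.seed(seed)
  mols <- lapply(seq_len(n), function(i) {
    data.frame(element = c("C", "C", "Br"),
               x = c(0, 1.4, 2.8) + rnorm(3, sd = 0.3),
               y = c(0, 0, 0.5) + rnorm(3, sd = 0.3),
               z = rnorm(3, sd = 0.3),
               charge = c(-0.1, 0.15, -0.05) + rnorm(3, sd = 0.05))
  })
  names(mols) <- paste0("m", seq_len(n))
  conformer_set(mols)
}
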