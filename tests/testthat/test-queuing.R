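test_that("single_score maps ranks linearly onto [0, 100]", {
  expect_equal(single_score(1, 177), 100)
  expect_equal(single_score(177, 177), 0)
  expect_equal(single_score(89, 177), 50)
  # vectorized and linear in k
  k <- 1:10
  expect_equal(diff(single_score(k, 10)), rep(-100 / 9, 9))
  expect_error(single_score(1, 1), "n must be")
  expect_error(single_score(0, 5), "rank k")
  expect_error(single_score(6, 5), "rank k")
})

test_that("rank_descending ranks larger scores first and handles ties", {
  expect_equal(rank_descending(c(63.4, 22.1, 50.7)), c(1, 3, 2))
  expect_equal(rank_descending(c(5, 5, 1)), c(1.5, 1.5, 3))
  expect_equal(rank_descending(c(5, 5, 1), "min"), c(1, 1, 3))
  expect_equal(rank_descending(c(5, 5, 1), "ordinal"), c(1, 2, 3))
  expect_error(rank_descending(c(1, NA, 3), ids = c("a", "b", "c")), "b")
})

test_that("composite_scores reproduces hand-computed toys", {
  # {A:(PS=10,MS=20), B:(PS=20,MS=10)}: SS are (0,100) and (100,0)
  res <- composite_scores(toy_score_table(c(10, 20), c(20, 10)))
  expect_equal(res$CS, c((0 * 10 + 100 * 20) / 30,
                         (100 * 20 + 0 * 10) / 30))
  # equal single scores => CS equals them, any positive weights (convexity)
  res2 <- composite_scores(toy_score_table(c(3, 2, 1), c(30, 20, 10)))
  expect_equal(res2$SS_PS, res2$SS_MS)
  expect_equal(res2$CS, res2$SS_PS)
  res3 <- composite_scores(toy_score_table(c(3, 2, 1), c(30, 20, 10)),
                           weight_mode = "fixed", weights = c(PS = 7, MS = 2))
  expect_equal(res3$CS, res2$CS)
})

test_that("composite_scores validates inputs and shrinks n on missing rows", {
  tab <- toy_score_table(c(1, 2, 3), c(4, NA, 6))
  expect_warning(res <- composite_scores(tab), "excluding 1")
  expect_equal(attr(res, "n"), 2L)
  expect_setequal(res$molecule_id, c("1", "3"))
  expect_error(composite_scores(toy_score_table(c(1, -2), c(3, 4))),
               "nonpositive weight")
  expect_error(composite_scores(toy_score_table(1, 2)), "at least 2")
})

test_that("CS lies between the endpoint single scores (convexity)", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    res <- composite_scores(toy_score_table(runif(n, 1, 100), runif(n, 1, 100)))
    lo <- pmin(res$SS_PS, res$SS_MS); hi <- pmax(res$SS_PS, res$SS_MS)
    expect_true(all(res$CS >= lo - 1e-9 & res$CS <= hi + 1e-9))
    expect_true(all(res$SS_PS >= 0 & res$SS_PS <= 100))
  }
})

test_that("untied single scores sum to 100 n / 2 (arithmetic series)", {
  set.seed(7)
  for (n in c(2, 5, 31)) {
    res <- composite_scores(toy_score_table(sample(seq_len(n)) + 0.5,
                                            runif(n, 1, 2)))
    expect_equal(sum(res$SS_PS), 100 * n / 2)
  }
})

test_that("CS is invariant under uniform rescaling of fixed weights", {
  tab <- toy_score_table(c(9, 4, 7, 2), c(1, 8, 3, 6))
  a <- composite_scores(tab, weight_mode = "fixed", weights = c(PS = 2, MS = 5))
  b <- composite_scores(tab, weight_mode = "fixed",
                        weights = c(PS = 2, MS = 5) * 13.7)
  expect_equal(a$CS, b$CS)
})

test_that("raising one molecule's PS never lowers its CS (fixed weights)", {
  # Under per-molecule docking-score weights this monotonicity can fail:
  # raising PS also raises the weight on SS_P, which may be the worse single
  # score (e.g. PS 10 -> 12 with MS 20 in a 2-molecule cohort lowers CS from
  # 66.67 to 62.5). With fixed weights SS_P is non-decreasing in PS and the
  # weights do not move, so CS is monotone.
  set.seed(11)
  w <- c(PS = 1, MS = 1)
  for (rep in 1:10) {
    n <- 12
    ps <- runif(n, 10, 60); ms <- runif(n, 10, 60)
    base <- composite_scores(toy_score_table(ps, ms),
                             weight_mode = "fixed", weights = w)
    i <- sample(n, 1)
    ps2 <- ps; ps2[i] <- ps2[i] * 1.25
    bumped <- composite_scores(toy_score_table(ps2, ms),
                               weight_mode = "fixed", weights = w)
    expect_gte(bumped$CS[i], base$CS[i] - 1e-9)
  }
})

test_that("vectorized CS equals the brute-force per-molecule oracle", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    ps <- round(runif(n, 5, 70), 2); ms <- round(runif(n, 5, 70), 2)
    if (rep %% 5 == 0) ps[2] <- ps[1]  # exercise ties
    expect_equal(composite_scores(toy_score_table(ps, ms))$CS,
                 cs_bruteforce(ps, ms), tolerance = 1e-12)
  }
})

test_that("tied inputs give permutation-invariant output under average ties", {
  tab <- toy_score_table(c(5, 5, 5, 1), c(2, 2, 9, 9))
  perm <- c(3, 1, 4, 2)
  a <- composite_scores(tab)
  b <- composite_scores(tab[perm, ])
  expect_equal(b$CS[order(perm)], a$CS)
})
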