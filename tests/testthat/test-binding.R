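table7 <- function() read_interactions(fixture("table7_interactions.csv"))

sub7 <- function(lig, rec) {
  t7 <- table7()
  t7[t7$ligand == lig & t7$receptor == rec, ]
}

test_that("bond_stats reproduces the worked contact means", {
  b1 <- bond_stats(sub7("BDEs-3", "1CNF"))
  a1 <- bond_stats(sub7("BDEs-3-19", "1CNF"))
  b2 <- bond_stats(sub7("BDEs-3", "1L7V"))
  a2 <- bond_stats(sub7("BDEs-3-19", "1L7V"))
  expect_equal(round(b1$mean_distance, 2), 4.61)
  expect_equal(round(a1$mean_distance, 2), 4.19)
  expect_equal(round(b2$mean_distance, 2), 4.66)
  # the fourth printed mean (3.93) was truncated, not rounded: the mean of
  # the seven listed distances is 3.9371 (its own 15.42% decrease confirms)
  expect_equal(a2$mean_distance, 3.93714, tolerance = 1e-5)
  expect_equal(b1$n_contacts, 9L)
  expect_equal(a2$n_contacts, 7L)
})

test_that("halogen-bond counts and residue bookkeeping", {
  expect_equal(bond_stats(sub7("BDEs-3", "1CNF"))$halogen_bonds, 0L)
  expect_equal(bond_stats(sub7("BDEs-3-19", "1L7V"))$halogen_bonds, 2L)
  a1 <- bond_stats(sub7("BDEs-3-19", "1CNF"))
  expect_equal(a1$halogen_bonds, 1L)
  # FAD271 contributes 3 distances but is not an amino acid
  expect_equal(a1$n_contacts, 8L)
  expect_equal(a1$n_residues, 4L)
  expect_false(any(startsWith(a1$hydrophobic_residues, "FAD")))
  b1 <- bond_stats(sub7("BDEs-3", "1CNF"))
  expect_equal(b1$n_residues, 7L)
  # LEU23, VAL27, LEU79, LEU182, LEU183 of 7 distinct amino acids
  expect_equal(b1$hydrophobic_fraction, 5 / 7)
})

test_that("bond_stats mean equals a brute-force flat average on random tables", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    tab <- data.frame(ligand = "L", receptor = "R",
                      residue = paste0("ALA", sample(1:99, n, replace = TRUE)),
                      distance_A = round(runif(n, 2, 6), 2),
                      bond_type = sample(c("Alkyl", "Br", "P-Alkyl"), n, TRUE))
    expect_equal(bond_stats(tab)$mean_distance,
                 sum(tab$distance_A) / n, tolerance = 1e-12)
  }
  expect_error(bond_stats(table7()[0, ]), "empty")
})

test_that("length_change uses unrounded means", {
  b1 <- bond_stats(sub7("BDEs-3", "1CNF"))
  a1 <- bond_stats(sub7("BDEs-3-19", "1CNF"))
  b2 <- bond_stats(sub7("BDEs-3", "1L7V"))
  a2 <- bond_stats(sub7("BDEs-3-19", "1L7V"))
  expect_equal(round(length_change(b1, a1), 2), 9.10)
  expect_equal(round(length_change(b2, a2), 2), 15.42)
  # rounding the means first would give the wrong 15.67%
  expect_equal(round((4.66 - 3.93) / 4.66 * 100, 2), 15.67)
  expect_equal(length_change(b1, b1), 0)
})

test_that("mmpbsa_ledger enforces the bookkeeping identities", {
  d <- mmpbsa_ledger(-50, -30, -10)
  expect_equal(d$g_bind, -10)
  d2 <- mmpbsa_ledger(-50, -30, -10, e_gas = -70, ts_gas = 0,
                      g_polar = -8, g_nonpolar = 3)
  expect_equal(d2$g_solvation, -5)
  expect_equal(d2$g, -75)
  # zero entropy and zero solvation: G reduces to E_gas
  d3 <- mmpbsa_ledger(-50, -30, -10, e_gas = -70, g_polar = 0, g_nonpolar = 0)
  expect_equal(d3$g, -70)
  # term ledger must sum to the total
  expect_silent(mmpbsa_ledger(-50, -30, -10,
                              terms = c(vdw = -6, elec = -4)))
  expect_error(mmpbsa_ledger(-50, -30, -10, terms = c(vdw = -6, elec = -3)),
               "residual")
  expect_error(mmpbsa_ledger(-50, -30, -10, terms = c(-6, -4)), "named")
})

test_that("mmpbsa identities hold for randomized consistent inputs", {
  set.seed(9)
  for (rep in 1:20) {
    gc_ <- rnorm(1, -50, 10); gp <- rnorm(1, -30, 5); gl <- rnorm(1, -10, 3)
    pol <- rnorm(1, -8); np <- rnorm(1, 3)
    d <- mmpbsa_ledger(gc_, gp, gl, g_polar = pol, g_nonpolar = np)
    expect_equal(d$g_bind, gc_ - gp - gl, tolerance = 1e-12)
    expect_equal(d$g_solvation, pol + np, tolerance = 1e-12)
  }
})

test_that("term_change_rates mirrors the published sign convention", {
  before <- c(vdw = -100, polar = -50)
  after <- c(vdw = -100, polar = -61.855)
  rates <- term_change_rates(before, after)
  expect_equal(rates$rate_pct[rates$term == "polar"], -23.71)
  expect_equal(rates$rate_pct[rates$term == "vdw"], 0)
  expect_equal(attr(rates, "largest"), "polar")
  # identical ledgers: all zero
  expect_true(all(term_change_rates(before, before)$rate_pct == 0))
  # zero-before, nonzero-after is undefined and excluded from the argmax
  r2 <- term_change_rates(c(a = 0, b = -10), c(a = 5, b = -11))
  expect_true(r2$undefined[r2$term == "a"])
  expect_equal(attr(r2, "largest"), "b")
  # zero both sides reports 0
  r3 <- term_change_rates(c(a = 0, b = -10), c(a = 0, b = -10))
  expect_equal(r3$rate_pct, c(0, 0))
  expect_error(term_change_rates(c(a = 1), c(b = 1)), "do not match")
})
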