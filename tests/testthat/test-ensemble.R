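cond <- thermo_conditions()

test_that("total free energy sums gas, thermal and solvation components", {
  ct <- make_conformers("X", gas = c(0, -100, 1.5), th_w = c(0, 10, 0.25),
                        th_o = c(0, 0, 0), ds_w = c(0, -5, -2), ds_o = c(0, 0, 0))
  expect_equal(unname(total_free_energy(ct, "water")), c(0, -95, -0.25))
  # missing octanol component names the compound and conformer
  ct$dgsolv_octanol_kcal[2] <- NA
  expect_error(total_free_energy(ct, "octanol"), "compound X, conformer c02")
})

test_that("Boltzmann weights normalize, preserve order and match examples", {
  expect_equal(boltzmann_weights(c(5, 5, 5), cond), rep(1 / 3, 3))
  expect_equal(boltzmann_weights(0, cond), 1)
  expect_equal(boltzmann_weights(c(0, rt(cond) * log(2)), cond), c(2 / 3, 1 / 3),
               tolerance = 1e-9)
  expect_error(boltzmann_weights(numeric(0), cond), "empty ensemble")
  # property: normalization for random ensembles, including huge magnitudes
  set.seed(42)
  for (i in 1:25) {
    g <- runif(sample(1:20, 1), -1e6, 1e6)
    w <- boltzmann_weights(g, cond)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("ensemble free energy matches log-sum-exp identities and the oracle", {
  expect_equal(ensemble_free_energy(3.7, cond), 3.7)
  expect_equal(ensemble_free_energy(c(0, 0), cond), -rt(cond) * log(2),
               tolerance = 1e-5)
  expect_equal(ensemble_free_energy(c(0, 0), cond), -0.41069, tolerance = 1e-4)
  expect_lt(abs(ensemble_free_energy(c(0, 100), cond)), 1e-12)
  # brute-force equivalence for small ensembles in [-10, 10]
  set.seed(7)
  for (i in 1:50) {
    g <- runif(sample(1:6, 1), -10, 10)
    expect_equal(ensemble_free_energy(g, cond), oracle_lse(g, cond),
                 tolerance = 1e-10)
    expect_equal(boltzmann_weights(g, cond), oracle_weights(g, cond),
                 tolerance = 1e-10)
  }
})

test_that("shifting every conformer by c shifts the ensemble free energy by c", {
  set.seed(13)
  for (i in 1:20) {
    g <- runif(sample(2:10, 1), -20, 20)
    c0 <- runif(1, -50, 50)
    expect_equal(ensemble_free_energy(g + c0, cond),
                 ensemble_free_energy(g, cond) + c0, tolerance = 1e-9)
    expect_equal(boltzmann_weights(g + c0, cond), boltzmann_weights(g, cond),
                 tolerance = 1e-12)
  }
})

test_that("ensemble free energy is bounded by the minimum and the degeneracy bound", {
  set.seed(5)
  for (i in 1:20) {
    g <- runif(sample(1:20, 1), -30, 10)
    ge <- ensemble_free_energy(g, cond)
    expect_lte(ge, min(g) + 1e-12)
    expect_gte(ge, min(g) - rt(cond) * log(length(g)) - 1e-12)
  }
})

test_that("compound log P reduces to the scalar transfer cycle for one conformer", {
  ct <- make_conformers("A", gas = -20, th_w = 2, th_o = 2, ds_w = -5, ds_o = -5)
  expect_equal(compound_logp(ct, cond)$logp, 0)
  ct2 <- make_conformers("A", gas = -20, th_w = 2, th_o = 2,
                         ds_w = -5, ds_o = -6.36424)
  expect_equal(compound_logp(ct2, cond)$logp, 1.0, tolerance = 1e-3)
})

test_that("two-phase ensemble log P matches the closed-form log-sum-exp oracle", {
  # conformer A dominates in water, B in octanol
  ct <- make_conformers("A", gas = c(-30, -30), th_w = c(1, 1), th_o = c(1, 1),
                        ds_w = c(-8, -4), ds_o = c(-3, -7))
  got <- compound_logp(ct, cond)
  gw <- oracle_lse(c(-30 + 1 - 8, -30 + 1 - 4), cond)
  go <- oracle_lse(c(-30 + 1 - 3, -30 + 1 - 7), cond)
  expect_equal(got$logp, (gw - go) / rt_ln10(cond), tolerance = 1e-10)
  expect_equal(sum(got$water$weights), 1, tolerance = 1e-12)
  expect_gt(got$water$weights[["c01"]], 0.5)
  expect_gt(got$octanol$weights[["c02"]], 0.5)
})

test_that("a conformer 25 RT above the minimum is thermodynamically irrelevant", {
  ct <- make_conformers("A", gas = c(-10, -10), th_w = c(0, 0), th_o = c(0, 0),
                        ds_w = c(-2, -1), ds_o = c(-3, -2))
  base <- compound_logp(ct, cond)$logp
  hi <- -10 - 2 + 26 * rt(cond) # >= min + 25 RT in both phases
  ct2 <- make_conformers("A", gas = c(-10, -10, 10 + hi), th_w = c(0, 0, 0),
                         th_o = c(0, 0, 0), ds_w = c(-2, -1, -10),
                         ds_o = c(-3, -2, -10))
  expect_lt(abs(compound_logp(ct2, cond)$logp - base), 1e-8)
})

test_that("at very low temperature the ensemble free energy approaches the minimum", {
  cold <- thermo_conditions(temperature = 1)
  g <- c(0, 0.5, 1.2, 3.0)
  expect_lt(abs(ensemble_free_energy(g, cold) - min(g)), 1e-2)
})

test_that("weighted-mean aggregation drops the conformational entropy term", {
  ct <- make_conformers("A", gas = c(0, 0), th_w = c(0, 0), th_o = c(0, 0),
                        ds_w = c(-2, -2), ds_o = c(-2, -2))
  # degenerate conformers: identical phases, both rules give log P = 0
  expect_equal(compound_logp(ct, cond, "weighted_mean")$logp, 0)
  # weighted mean of degenerate levels is the level itself (no -RT ln 2)
  ct2 <- make_conformers("A", gas = c(0, 0), th_w = c(0, 0), th_o = c(0, 0),
                         ds_w = c(-2, -2), ds_o = c(-2, -3))
  fe <- compound_logp(ct2, cond, "free_energy")
  wm <- compound_logp(ct2, cond, "weighted_mean")
  expect_equal(wm$water$ensemble_free_energy, -2)
  expect_equal(fe$water$ensemble_free_energy, -2 - rt(cond) * log(2),
               tolerance = 1e-9)
})

test_that("logp_table covers all compounds and rejects mixed single-compound input", {
  ct <- rbind(make_conformers("B", -10, 0, 0, -2, -4),
              make_conformers("A", -10, 0, 0, -3, -3))
  tab <- logp_table(ct, cond)
  expect_equal(tab$compound_id, c("A", "B"))
  expect_equal(tab$logp[1], 0)
  expect_error(compound_logp(ct, cond), "single compound")
})

test_that("redundancy pruning groups by energy window and keeps the minimum", {
  ct <- make_conformers("A", gas = c(0, 0.5, 10), th_w = c(0, 0, 0),
                        th_o = c(0, 0, 0), ds_w = c(0, 0, 0), ds_o = c(0, 0, 0),
                        ids = c("c01", "c02", "c03"))
  expect_identical(prune_redundant(ct, "water", 0), ct)
  pruned <- prune_redundant(ct, "water", 1.0)
  expect_equal(pruned$conformer_id, c("c01", "c03"))
  # identical energies: lexicographically smallest id survives
  ct2 <- make_conformers("A", gas = c(0, 0), th_w = c(0, 0), th_o = c(0, 0),
                         ds_w = c(0, 0), ds_o = c(0, 0), ids = c("c09", "c02"))
  expect_equal(prune_redundant(ct2, "water", 1e-6)$conformer_id, "c02")
  expect_error(prune_redundant(ct, "water", -1), "non-negative")
})
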