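cond <- thermo_conditions()
prot <- proton_parameters()

ms <- function(id, q, g, cid = "X") microstate(id, cid, q, g)

test_that("microstate free energy is the conformer log-sum-exp", {
  expect_equal(microstate_free_energy(ms("m1", 0, 4.2), cond), 4.2)
  expect_equal(microstate_free_energy(ms("m1", 0, c(1, 1)), cond),
               1 - rt(cond) * log(2), tolerance = 1e-9)
  expect_equal(microstate_free_energy(ms("m1", 0, c(0, 1, 2)), cond),
               oracle_lse(c(0, 1, 2), cond), tolerance = 1e-10)
})

test_that("microscopic pKa follows the deprotonation cycle and charge rules", {
  acid <- ms("a", 0, proton_total(prot) - 5)
  base <- ms("b", -1, -5)
  expect_equal(micro_pka(acid, base, prot, cond), 0)
  expect_equal(micro_pka(ms("a", 0, 0), ms("b", -1, 271.65424), prot, cond),
               1.0, tolerance = 1e-3)
  expect_error(micro_pka(ms("a", 0, 0), ms("b", 0, 0), prot, cond),
               "charge mismatch")
})

test_that("doubling base tautomer degeneracy lowers the micro pKa by log10(2)", {
  acid <- ms("a", 0, 0)
  p1 <- micro_pka(acid, ms("b", -1, c(270)), prot, cond)
  p2 <- micro_pka(acid, ms("b", -1, c(270, 270)), prot, cond)
  expect_equal(p2 - p1, -log10(2), tolerance = 1e-9)
})

test_that("macroscopic pKa collapses to the micro pKa for one tautomer per charge", {
  set <- microstate_set("X", list(ms("a", 0, c(0, 0.5)), ms("b", -1, c(270, 271))))
  res <- macro_pka(set, 0L, prot, cond)
  expect_s3_class(res, "pka_result")
  expect_equal(nrow(res$micro_pkas), 1)
  expect_equal(res$macro_pka, res$micro_pkas$pka[1], tolerance = 1e-12)
})

test_that("degenerate tautomers shift the macroscopic pKa by +/- log10(2)", {
  acid <- ms("a", 0, 0)
  base1 <- ms("b1", -1, 270); base2 <- ms("b2", -1, 270)
  one <- macro_pka(microstate_set("X", list(acid, base1)), 0L, prot, cond)
  two <- macro_pka(microstate_set("X", list(acid, base1, base2)), 0L, prot, cond)
  expect_equal(two$macro_pka, one$macro_pka - log10(2), tolerance = 1e-9)
  acid2 <- ms("a2", 0, 0)
  twoa <- macro_pka(microstate_set("X", list(acid, acid2, base1)), 0L, prot, cond)
  expect_equal(twoa$macro_pka, one$macro_pka + log10(2), tolerance = 1e-9)
})

test_that("hierarchical microstate collapse equals flat conformer pooling", {
  set.seed(31)
  for (i in 1:20) {
    confs <- lapply(1:sample(2:4, 1), function(j) runif(sample(1:5, 1), -10, 10))
    flat <- ensemble_free_energy(unlist(confs), cond)
    hier <- ensemble_free_energy(
      vapply(confs, ensemble_free_energy, numeric(1), cond = cond), cond)
    expect_equal(hier, flat, tolerance = 1e-10)
  }
})

test_that("macro pKa matches the direct-exponential oracle on random microstate sets", {
  set.seed(17)
  for (i in 1:20) {
    acids <- lapply(seq_len(sample(1:3, 1)), function(j)
      ms(paste0("a", j), 0, runif(sample(1:3, 1), -10, 0)))
    bases <- lapply(seq_len(sample(1:3, 1)), function(j)
      ms(paste0("b", j), -1, runif(sample(1:3, 1), 265, 280)))
    res <- macro_pka(microstate_set("X", c(acids, bases)), 0L, prot, cond)
    want <- oracle_macro_pka(lapply(acids, `[[`, "conformer_free_energies"),
                             lapply(bases, `[[`, "conformer_free_energies"),
                             prot, cond)
    expect_equal(res$macro_pka, want, tolerance = 1e-9)
    # bracketing by the microscopic values
    nb <- length(bases); na <- length(acids)
    expect_gte(res$macro_pka, min(res$micro_pkas$pka) - log10(nb) - 1e-9)
    expect_lte(res$macro_pka, max(res$micro_pkas$pka) + log10(na) + 1e-9)
  }
})

test_that("shifting both charge states by a constant leaves the macro pKa unchanged", {
  acid <- ms("a", 0, c(0, 1)); base <- ms("b", -1, c(270, 272))
  p0 <- macro_pka(microstate_set("X", list(acid, base)), 0L, prot, cond)$macro_pka
  sh <- 7.3
  acid2 <- ms("a", 0, c(0, 1) + sh); base2 <- ms("b", -1, c(270, 272) + sh)
  p1 <- macro_pka(microstate_set("X", list(acid2, base2)), 0L, prot, cond)$macro_pka
  expect_equal(p1, p0, tolerance = 1e-9)
})

test_that("lowering a base conformer never raises the macro pKa, and vice versa", {
  set.seed(23)
  mk <- function(ga, gb) macro_pka(microstate_set("X", list(
    ms("a", 0, ga), ms("b", -1, gb))), 0L, prot, cond)$macro_pka
  for (i in 1:10) {
    ga <- runif(3, -5, 5); gb <- runif(3, 265, 275)
    p0 <- mk(ga, gb)
    gb2 <- gb; gb2[2] <- gb2[2] - 1.5
    expect_lte(mk(ga, gb2), p0 + 1e-12)
    ga2 <- ga; ga2[2] <- ga2[2] - 1.5
    expect_gte(mk(ga2, gb), p0 - 1e-12)
  }
})

test_that("missing charge states are reported by compound and charge", {
  set <- microstate_set("X", list(ms("a", 0, 0)))
  expect_error(macro_pka(set, 0L, prot, cond), "compound X.*charge -1")
})

test_that("microstate-table validation flags discrepancies beyond tolerance", {
  acid <- ms("a", 0, 0); base <- ms("b", -1, 270)
  set <- microstate_set("X", list(acid, base))
  truth <- macro_pka(set, 0L, prot, cond)$macro_pka
  ok <- validate_microstate_table(set, truth, tol = 0.1, proton = prot, cond = cond)
  expect_false(ok$flagged)
  expect_equal(ok$discrepancy, 0)
  bad <- validate_microstate_table(set, truth + 3.9, tol = 0.1,
                                   proton = prot, cond = cond)
  expect_true(bad$flagged)
  expect_equal(bad$discrepancy, -3.9, tolerance = 1e-9)
  expect_named(bad$microstate_free_energies, c("a", "b"))
})

test_that("long-table round trip through as_microstate_sets preserves the dialect", {
  df <- data.frame(compound_id = "X",
                   microstate_id = c("a", "a", "b"),
                   formal_charge = c(0L, 0L, -1L),
                   conformer_id = c("c1", "c2", "c1"),
                   free_energy_kcal = c(0, 1, 270))
  attr(df, "dialect") <- "absolute_aqueous"
  sets <- as_microstate_sets(df)
  expect_equal(macro_pka(sets$X, 0L, prot, cond)$macro_pka,
               oracle_macro_pka(list(c(0, 1)), list(270), prot, cond),
               tolerance = 1e-9)
  # relative dialect bypasses the proton term
  df2 <- df; df2$free_energy_kcal <- c(0, 1, 5.0)
  attr(df2, "dialect") <- "relative_transition"
  attr(df2, "reference") <- "a"
  tab <- pka_table(df2, cond = cond)
  expect_equal(tab$pka,
               (5.0 - oracle_lse(c(0, 1), cond)) / rt_ln10(cond),
               tolerance = 1e-9)
})
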