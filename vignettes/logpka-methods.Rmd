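---
title: "Ensemble free-energy prediction of log P and pKa: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble free-energy prediction of log P and pKa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logpka)
```

## The problem

Quantum-chemistry continuum-solvation calculations produce, per compound,
a set of conformer free-energy components: a gas-phase electronic energy,
a thermal (vibrational/rotational/translational) correction computed in
each solvent, and a solvation free energy in each solvent. `logpka`
implements everything downstream of those numbers for two observables of
drug-like molecules:

* **log P**, the base-10 logarithm of the n-octanol/water partition
  coefficient of the neutral species, from the water-to-octanol transfer
  free energy; and
* **pKa**, the acidity constant, from the aqueous deprotonation cycle over
  protonation microstates.

Both are ratios of partition functions, so the central primitive is the
Boltzmann collapse of a set of state free energies,
$G_\mathrm{ens} = -RT \ln \sum_i e^{-G_i/RT}$, evaluated throughout with a
minimum-energy shift so any finite input is overflow-safe.

## Thermodynamic cycles

For a neutral compound, the transfer free energy is the difference of the
two solvation free energies,
$\Delta\Delta G^{w \to o} = \Delta G^o_\mathrm{solv} - \Delta G^w_\mathrm{hyd}$,
and $\log P = -\Delta\Delta G^{w \to o} / (RT\ln 10)$. The sign convention
makes positive log P octanol-preferring (lipophilic), matching experimental
conventions.

For deprotonation HX $\rightarrow$ X$^-$ + H$^+$ in water,
$\Delta G_\mathrm{aq} = G_\mathrm{aq}(\mathrm{X}^-) + G_\mathrm{aq}(\mathrm{H}^+) - G_\mathrm{aq}(\mathrm{HX})$
and $\mathrm{p}K_a = \Delta G_\mathrm{aq}/(RT\ln 10)$. The aqueous proton
free energy is the experimental value −270.29 kcal/mol, decomposed as the
gas-phase free energy of the proton (−6.28), the 1 atm → 1 M standard-state
correction at 298 K (+1.89) and the proton hydration free energy (−265.9);
all three are exposed (and overridable) in `proton_parameters()`.

Units are kcal/mol end to end; there is no unit auto-detection. The working
conditions default to T = 298.15 K with R = 1.98720425 × 10⁻³
kcal mol⁻¹ K⁻¹ (`thermo_conditions()`). The conventional thermochemical
298.15 K was chosen over a nominal 298 K; the difference is below 0.001 in
either observable, far below the precision of any quantity involved, so the
choice is inconsequential but fixed.

## Conformer ensembles and log P

Each compound is a set of conformers; in each solvent a conformer's total
free energy is gas energy + that solvent's thermal correction + that
solvent's solvation free energy. The per-phase ensemble free energy is the
log-sum-exp over these totals, with Boltzmann populations computed per
phase (no cross-phase weight sharing: geometries and thermal corrections
are solvent-specific). Then
$\log P = (G^w_\mathrm{ens} - G^o_\mathrm{ens})/(RT\ln 10)$.

Two aggregation rules are implemented because "Boltzmann-weighted" is
genuinely ambiguous between them:

* `free_energy` (default): the partition-function rule above. It reduces
  to the scalar transfer cycle for a single conformer and correctly adds
  the conformational-entropy term $-RT\ln n$ for $n$ degenerate
  conformers.
* `weighted_mean`: the Boltzmann-weighted arithmetic mean of the conformer
  totals in each phase. This drops the entropy term and is retained purely
  for sensitivity analysis; the two rules differ by at most $RT\ln n$
  (≈ 1.8 kcal/mol at 20 conformers), usually much less.

`prune_redundant()` stands in for manual removal of duplicate
conformations: conformers whose totals in a chosen solvent agree pairwise
within a window are collapsed to their lowest-energy member (ties broken
by lexicographic id; the global minimum is never removed; a window of 0
disables pruning). The default window of 10⁻⁶ kcal/mol removes only
numerical duplicates. Geometric (RMSD-based) pruning is out of scope —
geometries are not part of the data model.

## Microstates and macroscopic pKa

A microstate is one protonation/tautomeric form at a defined formal
charge, carrying aqueous free energies for its conformers. The
macroscopic free energy of a total-charge state is the log-sum-exp over
*all conformers of all its microstates*. Flat pooling equals collapsing
each microstate first and then pooling microstates — an algebraic identity
of log-sum-exp that the test suite checks explicitly — so the macroscopic
pKa between charges $q$ and $q-1$ is well defined and reproduces the
single-tautomer case exactly. Tautomeric degeneracy behaves as statistics
requires: duplicating a deprotonated tautomer lowers the macroscopic pKa
by $\log_{10} 2$, duplicating a protonated one raises it by the same
amount. Multiprotic ladders are supported for any adjacent charge pair,
though the shipped data set is monoprotic (0 → −1).

Two input dialects are accepted and must be declared in the file header,
never guessed: `absolute_aqueous` free energies (the proton term is added
by the cycle) and `relative_transition` free energies (deprotonation free
energies relative to a reference microstate with the proton/gas terms
already folded in; the proton term is bypassed). Guessing would be unsafe
because the two dialects differ by ~270 kcal/mol on anions but are
indistinguishable on shifted scales.

### Validating submitted microstate tables

`validate_microstate_table()` recomputes the macroscopic pKa from a table
and flags disagreement with a reported value beyond a tolerance
(default 0.10 pKa units, the level at which independent recomputations of
the same submission typically agree). One structural fact is worth
stating because it shapes what this validator can and cannot catch:
exchanging the complete free-energy sets of two microstates *of the same
charge* merely relabels the pooled partition function and provably cannot
change the macroscopic value — `corrupt_microstates()` therefore produces
tables whose macroscopic pKa is untouched (a property the tests assert),
while the per-microstate free energies it scrambles are still reported
for inspection. The damaging real-world error class is a value
misassigned *across* charge states (e.g. a neutral tautomer's transition
free energy swapped with the anion's in a submission file). Two shipped
fixtures with synthetic, back-solved energies reproduce that class at the
magnitudes observed in practice: a tautomer-flip table whose recomputed
value sits 3.90 pKa units from the reported one, and a mis-weighted
conformer ensemble reported as 7.24 whose energies recompute to 3.30.
Their energies are invented (filenames say `synthetic_`); only the
discrepancy structure is meaningful.

## Evaluation statistics

`prediction_records()` pairs calculated with experimental values and
parses censored measurements ("> 12.00") which are excluded from every
statistic, count and flag — no Tobit-style treatment is attempted. With
delta = calculated − experimental over non-excluded records:
rmsd = $\sqrt{\overline{\delta^2}}$, mse = $\overline{\delta}$ (signed),
mue = $\overline{|\delta|}$, and Pearson's sample r between the two
columns (r, not r²). The inequalities rmsd ≥ mue ≥ |mse| hold on any
input and are property-tested. Outlier flagging is strict
(|delta| > threshold, default 1.50 property units), and
`summarize_excluding()` recomputes statistics after removing flagged
compounds. `pair_shifts()` reports experimental differences across
matched substituent pairs (e.g. methyl → phenyl replacements) and their
mean.

The shipped SAMPL7 reference tables preserve two details of the original
data: the two "> 12.00" pKa bounds (SM28, SM33), and the dual SM25 value —
the originally submitted 7.24 is the default used in statistics (it is
what the table's error column reflects), with the post-correction 3.30
carried as an annotation. Metrics are computed at full precision;
comparisons against published two-decimal values are made after rounding.

## The synthetic-data generator

`generate_synthetic()` emulates the *data model* of a continuum-solvation
study — multi-conformer, multi-tautomer free-energy tables — with known
ground truth, so the whole pipeline is testable without any
electronic-structure calculation. Per compound it draws the target log P
and macroscopic pKa uniformly from their ranges, draws components at
plausible magnitudes (gas energies in [−50, 0], thermal corrections in
[0, 5], solvation free energies in [−15, 0] kcal/mol; tautomer offsets up
to 3 and conformer spreads up to 2 kcal/mol), then back-solves one block
per observable — a constant added to all octanol solvation energies, and
a constant added to all deprotonated-state energies — so the embedded
targets are *exact*, by the shift property of log-sum-exp. This makes
noise-free recovery a sharp 10⁻⁹ invariant rather than a statistical one.
Gaussian noise of a chosen sd is added to every component afterwards.

Default ranges (log P in [−0.5, 4.5], pKa in [4, 12], 1–20 conformers,
1–3 tautomers per charge) mirror the spread of the sulfonamide set the
reference tables describe. What the generator does *not* emulate: any
structure–energy relationship (no geometries, no SMILES), correlated
errors between components, or systematic continuum-model bias. Passing
recovery tests therefore demonstrates the correctness of the
thermodynamic bookkeeping, not the accuracy of any solvation model on
real molecules.

Noise propagates at the expected rate: with sd = 0.5 kcal/mol on each of
the four phase-specific components, the delta-method rate
$\sqrt{4}\,\sigma/(RT\ln 10) \approx 0.73$ log units agrees within 20%
with the empirical truth-recovery rmsd (0.765 in a 10,000-compound run of
this generator; the test suite checks a 200-compound draw against that
reference). The gas-phase term cancels between phases and contributes
only through conformer reweighting.

## Numerical choices and degenerate inputs

* Log-sum-exp and Boltzmann weights are always computed with a
  minimum-energy shift; inputs up to ±10⁶ kcal/mol are safe by contract.
* Empty ensembles, non-finite energies, charge gaps (no microstate at a
  requested charge), undeclared dialects, duplicate table keys and
  malformed numbers are all distinct, named errors carrying the compound,
  conformer or line involved; nothing is silently dropped.
* Determinism: table outputs are sorted by id (radix order, locale-free);
  the generator is byte-reproducible given a spec and seed.
* CSV output is written at 4 decimals for display with a full-precision
  sidecar for round-tripping.

## Problem sizes

The test suite and the reproduction script run the reference tables
(22 compounds) directly, property checks over a few dozen randomized
small ensembles, and synthetic recovery at 200–300 compounds — sizes at
which every check completes in seconds on one core while keeping sampling
error in the noise-propagation checks well inside their bands.

## Known limitations

* No microstate enumeration from structure, tautomer generation or
  pH-dependent population curves.
* No censored-regression treatment of bounded measurements; they are
  excluded, which matches how the reference statistics were defined but
  discards information.
* The macroscopic-pKa validator compares one number per compound; it
  cannot detect same-charge relabelings (invisible to the partition
  function) and localizes cross-charge errors only as far as the
  per-microstate free energies it reports.
* Conformer pruning is energetic only; two genuinely different
  conformations at coincidentally equal energies would be merged at a
  loose window.
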