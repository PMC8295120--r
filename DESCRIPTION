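Package: logpka
Title: Conformer-Ensemble Prediction of log P and pKa from Continuum-Solvation Free Energies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-processing workflow for quantum-chemistry continuum-solvation
    output: Boltzmann-weighted conformer-ensemble free energies in water and
    n-octanol yield the octanol/water partition coefficient (log P) via the
    transfer free-energy cycle, and aqueous microstate free energies yield
    microscopic and macroscopic acid dissociation constants (pKa) via the
    deprotonation cycle with the experimental aqueous proton free energy.
    Includes paired prediction-versus-experiment statistics (rmsd, signed and
    unsigned mean errors, Pearson correlation) with censored-measurement
    handling, outlier flagging, matched-pair substituent-shift analysis, a
    microstate-table consistency validator, and a synthetic free-energy
    ensemble generator with exact embedded ground truth for end-to-end
    pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
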