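Package: pepqsar
Title: SAR and Physics-Based QSAR Analysis of Ultra-Short GLP-1 Receptor Agonist Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for structure-activity analysis of ultra-short (11-mer)
    GLP-1 receptor agonist peptides: potency conversions and the
    Ala/Aib-scanning decomposition of the Calpha-methylation contribution to
    agonist potency; 26 physics-based receptor-peptide interface descriptors
    (interaction counts and energies, packing and model-quality scores, and a
    binding-energy decomposition with implicit solvation) computed from PDB
    coordinates; a stepwise multiple linear regression QSAR engine with the
    full validation ladder (adjusted R-squared, F- and t-tests, variance
    inflation factors, AIC/AICc, leave-one-out Q-squared, Y-randomization and
    cRp-squared); potency-matched and potency-ranked train/test split
    constructions with external prediction assessment; and seeded synthetic
    data generators so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, withr
Suggests: testthat (>= 3.0.0), bio3d, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
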