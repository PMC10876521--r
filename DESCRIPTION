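Package: deutrace
Title: Comparative Metabolomics and Deuterium Tracer-Fate Analysis for Branched Fatty Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative untargeted LC-HRMS metabolomics of
    C. elegans beta-branched fatty acids and for stable-isotope (deuterium)
    tracer experiments. Implements the feature-table statistics used in
    two-genotype volcano analyses (retention-time culling, blank
    subtraction, intensity filtering, internal-reference normalization,
    Welch t-tests with Benjamini-Hochberg FDR control), detection of
    deuterium-labeled isotopologue partners at exact n x (m(2H) - m(1H))
    mass offsets, and a deterministic tracer-fate model that propagates
    per-carbon deuterium labels through fatty-acid methylation,
    cyclopropanation, beta-oxidation, alpha-oxidation, and hydroxylation to
    predict product formulas, deuterium counts, and ion m/z. A seeded
    synthetic-data module generates feature tables with planted ground
    truth so every stage is testable without raw spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
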