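Package: histoneptm
Title: Quantification of Histone PTMs and Variants from Bottom-Up Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies relative abundances of histone post-translational
    modifications (PTMs), combinatorial PTM forms, and histone-variant marker
    peptides from centroided bottom-up LC-MS/MS runs of propionylated,
    trypsin-digested histones, following the targeted acquisition scheme used
    for Caenorhabditis elegans histones. Includes a monoisotopic mass engine
    with two-round propionylation rules, a machine-readable peptide/PTM
    catalog, extracted-ion-chromatogram construction and peak integration,
    discrimination of coeluting isobaric peptide forms via targeted MS2
    fragment ions, per-backbone and single-PTM ratio tables, batch-aware
    differential-PTM statistics with FDR control and hierarchical clustering,
    and a synthetic-run simulator with known ground truth for closed-loop
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
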