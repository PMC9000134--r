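Package: ppidisp
Title: Dispensable Content of Transient and Permanent Protein-Protein
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the fraction of completely dispensable
    protein-protein interactions (PPIs) among transient versus permanent
    interactions in a structural interactome. Provides a residue-level
    data model of the structural interactome with geometric interface
    detection (5 Angstrom atom-contact rule), template annotation by
    interface-residue coverage, mutually-exclusive-interface counting,
    missense-mutation filtering and interface mapping, five
    transient/permanent classifiers driven by binding free energy and
    expression data, structure-based edgotype prediction from binding
    energy changes, a Bayesian estimator of dispensable PPI content with
    log-scale (Bland) ratio-of-proportions confidence intervals,
    classifier validation metrics, and a seeded synthetic-data generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
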