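Package: dvnpchrom
Title: Nucleosome Displacement and Transcriptional Impairment by a Viral
    Nucleoprotein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how an ectopically expressed
    viral nucleoprotein (DVNP) remodels yeast chromatin. Converts aligned
    sequencing fragments (MNase-seq and ChIP-seq) into genome-mean or
    spike-in normalized per-base coverage, computes TSS-anchored metagene
    profiles with per-gene polyadenylation-site truncation, associates
    DVNP enrichment and sequence-encoded nucleosome stability with
    nucleosome occupancy loss via sliding-window quintile binning and
    Welch tests, estimates global RNA polymerase II occupancy changes with
    exogenous spike-in normalization, and analyses synthetic genetic array
    colony screens (relative growth, chi-squared gene-set tests,
    hypergeometric category enrichment). Includes a synthetic-data
    generator that plants known effect sizes so every pipeline stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
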