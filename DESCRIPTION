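Package: methmatch
Title: Cross-Tissue DNA Methylation Concordance in Matched Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of epigenome-wide DNA methylation concordance between
    two tissues sampled from the same subjects (e.g. matched bone and blood).
    Provides intensity-level quality control (detection p-value and SNP-probe
    filtering, beta/M-value computation, empirical-Bayes batch correction),
    identification of differentially methylated positions (DMPs) by moderated
    t-statistics with a paired-analysis cross-check, identification of
    similarly methylated positions (SMPs) by per-site within-subject Pearson
    correlation with FDR and beta-similarity filters, a subject-label
    permutation null for the SMP count, genomic-feature and CpG-island
    enrichment, disease-locus overlap counting, and hypergeometric gene-set
    over-representation. Includes a synthetic-data generator that plants
    SMP, DMP and null sites with known truth for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva
Config/testthat/edition: 3
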