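Package: centrotype
Title: Centroid-Correlation Molecular Subtyping and Subtype Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns molecular subtypes to gene-expression profiles by Spearman
    rank correlation against subtype centroids, implementing the full
    triple-negative breast cancer (TNBC) decision procedure: a correlation
    cutoff, a Fisher z-score test separating predominant from dual subtypes,
    an unstable (UNS) class, and an immunomodulatory (IM) overlay score.
    Includes gene-coverage gating, transcript-to-gene FPKM aggregation,
    log2/per-batch-centering preprocessing, a nearest-shrunken-centroids
    trainer for deriving reduced gene signatures, cross-algorithm and
    cross-condition concordance and stability reports, and a seeded synthetic
    cohort generator so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
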