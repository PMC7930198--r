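Package: dspHet
Title: Phenotype Heterogeneity Analysis for Digital Spatial Profiling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of GeoMx-style digital spatial profiling (DSP)
    experiments of multi-region tumor cohorts. Collapses probe-level RNA
    counts to gene counts after iterative Grubbs outlier-probe removal,
    derives per-region limits of quantitation from negative-control probes
    or IgG control antibodies, applies detection and quality-control
    filters, and provides negative, third-quartile (Q3), signal-to-noise
    and housekeeping normalizations. Scores gene signatures by combined
    z-scores, classifies regions and tumors into six androgen-receptor /
    neuroendocrine phenotype classes, embeds samples by classical
    multidimensional scaling, and quantifies intra-tumor, intra-patient and
    inter-patient phenotype concordance by exact and sampled pair agreement
    with bias-corrected and accelerated (BCa) bootstrap confidence
    intervals. Also includes rank-based differential expression, gapped-read
    quantification of the AR-V7 splice junction from SAM-subset alignment
    records, immunohistochemistry H-scores, and a seeded synthetic-data
    generator that emulates the probe-panel, antibody-panel and
    patient/tumor/region hierarchy of a DSP study so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
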