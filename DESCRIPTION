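Package: ftdcascade
Title: Biomarker Cascade Modelling in Genetic Frontotemporal Dementia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the order in which biomarkers become abnormal
    in autosomal-dominant frontotemporal dementia, with an emphasis on white
    matter hyperintensity (WMH) burden in progranulin (GRN) mutation carriers.
    Provides a synthetic cohort simulator with a known latent event cascade,
    normative age/sex adjustment of lesion volumes with nonparametric group
    comparisons (Kruskal-Wallis, Dunn post hoc, Cliff's delta), a
    discriminative event-based model (constrained Gaussian mixtures,
    probability-weighted rank aggregation, bootstrap positional-variance
    diagrams, patient staging with cross-validated AUC), and directional
    cross-lagged regressions of atrophy rates on baseline lesion load with
    false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, Epidemiology
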