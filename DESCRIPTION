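Package: colonoise
Title: Colony Growth Kinetics, Expression Noise and Metabolic Trade-Off Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking gene-expression noise to colony-level
    metabolic heterogeneity in bacteria. Segments and tracks colonies from
    flatbed-scanner plate time-lapses (temporal standard-deviation projection,
    per-plate Otsu thresholding, watershed), fits Gompertz growth curves to
    per-colony area traces to estimate maximum growth rate and lag time,
    estimates respiratory rates from the accumulation of a redox-dye signal
    (maximum-slope linear window), computes deviating expression noise from
    single-cell protein statistics with permutation-based gene-set and
    TF-target enrichment and Storey q-values, analyses Pareto-optimal
    trade-offs between growth rate and lag time, and runs mass-based ion
    annotation with differential-abundance and pathway statistics for
    untargeted metabolomics. Includes synthetic-data generators with known
    ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    fgsea,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
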