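Package: regustress
Title: Regulon-Level Analysis of Ethanol Stress Response and Adaptation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Tools for quantifying acute ethanol-stress responses and
        long-term adaptation from normalized gene-expression data in
        bacteria. Implements two differential-expression rules (a
        fold-change plus Wilcoxon rank-test rule for treatment-versus-
        control contrasts, and a unanimous-direction rule for evolved-
        versus-parent designs), regulon and gene-set response profiling
        with dose correlations and hypergeometric enrichment,
        classification of aberrantly expressed transcription units
        regulated by ethanol-binding transcription factors, and
        monotone/step-wise trend detection across adaptive-evolution
        time courses. Ships a synthetic-data generator with planted
        ground truth so every stage is testable without external
        downloads, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'aberrancy.R'
    'deg.R'
    'io.R'
    'synthesis.R'
    'trends.R'
    'response.R'
    'pipeline.R'
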