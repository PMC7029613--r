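Package: ipco
Title: Inference of Functional Profiles for 16S Data by Double Co-Inertia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers functional (pathway or gene-family) abundance profiles for
    16S amplicon samples from the co-variance between a paired reference
    taxonomic and functional dataset, via the RLQ (fourth-corner) cross
    product. Provides correspondence analysis of the reference taxonomic
    table, weighted-mean centering, the R'LQ association product with
    weighted-average re-standardisation, an RV-coefficient permutation test
    to qualify reference datasets, a menu of community-data transformations,
    bootstrap cross-validation with Spearman correlation summaries, a
    shuffled-reference null, coverage-based quality binning, metabolite
    association with multiplicity adjustment, and a paired-data simulator
    with a known taxon-by-function genome-content structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    optparse
Suggests:
    withr,
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
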