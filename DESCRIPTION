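Package: couplemap
Title: Harmonization and Meta-Analysis of GPCR-G Protein Coupling Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to harmonize heterogeneous quantitative GPCR-G protein
    coupling screens (Emax, pEC50, log(Emax/EC50)) with literature transducer
    annotations into a unified, classified coupling map. Implements inclusion
    and exclusion rules with a basal-SD detection threshold, cross-dataset
    concordance statistics and detection-threshold optimization, min-max Emax
    normalization with member-to-family aggregation, evidence classification
    (supported, novel, proposed, unique, missing), receptor promiscuity and
    G protein coverage statistics, G protein co-coupling matrices (Pearson,
    Jaccard, activation difference) with correlation-distance clustering,
    tissue-expression profiling of the 16 G protein genes, and a seeded
    synthetic-data generator emulating two biosensor assays plus a biased
    literature-annotation process for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
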