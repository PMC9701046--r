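Package: stcnet
Title: Expression Dynamics Analysis by Moderated F-Tests, Trend Profile
    Clustering, Enrichment and Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for short ordered-condition expression
    studies (e.g. control / challenged / post-resolution designs with few
    replicates): differential expression by the random-variance-model (RVM)
    moderated F-test with Benjamini-Hochberg false discovery rate control,
    clustering of expression dynamics onto enumerated unit-change model
    profiles (series test of cluster, STC) with permutation-based profile
    significance, Fisher / chi-squared gene-set over-representation from GMT
    annotations, and a thresholded Pearson co-expression network with degree,
    local clustering coefficient, k-core and hub ranking. Includes a
    synthetic-data generator with planted profiles, inverse-gamma gene
    variances, planted gene sets and a planted hub module, so that every
    stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
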