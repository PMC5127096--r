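Package: enterotyper
Title: Enterotype Clustering and Association Analysis for Fecal Microbiota Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based enterotype analysis of sample-by-taxon count
    tables: family-level aggregation, relative abundance and prevalence,
    alpha diversity (Shannon, Chao1, Good's coverage), square-root
    Jensen-Shannon divergence, UPGMA dendrograms, partitioning around
    medoids with Calinski-Harabasz model selection and prediction-strength
    and silhouette validation, PCA/PCoA ordination, stratified group
    comparisons with Holm correction and compact letter displays, Kendall
    tau-b correlation networks, and BMI-stratified comparisons. Includes a
    Dirichlet-multinomial cohort simulator with copula-coupled ordinal
    questionnaire scores for end-to-end testing of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
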