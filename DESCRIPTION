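Package: parkig
Title: Imaging Genetics of the Cortico-Basal Ganglia-Thalamocortical
    Circuit in Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An imaging-genetics analysis pipeline for Parkinson's disease
    built around structural connectivity of the eight-region cortico-basal
    ganglia-thalamocortical circuit.  Provides genotype quality control
    (minor-allele frequency, Hardy-Weinberg exact test, missingness,
    identity-by-state distances with classical multidimensional scaling),
    fiber-density connectome construction with weighted degree centrality
    and Bonferroni-corrected group comparisons, covariate-adjusted per-SNP
    additive-model association with permutation empirical p-values,
    backward stepwise regression of MDS-UPDRS clinical scores with
    sequential variance decomposition, and leave-one-out cross-validated
    prediction.  A synthetic-cohort generator with known ground truth
    makes every stage testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
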