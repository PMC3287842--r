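Package: rarepool
Title: Pooled Rare-Variant Association Tests and Their Evaluation by Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level pooled association tests for rare variants: the
    fixed-threshold burden tests (T1, T5), the weighted-sum test with
    inverse-variance allele-frequency weights, and the variable-threshold
    test that maximizes a score z-statistic over candidate minor-allele
    frequency cutoffs and assesses the maximum by phenotype permutation,
    re-optimizing the cutoff within every permutation. Includes two-stage
    covariate adjustment by linear residualization, an exome-like
    genotype/phenotype simulator with known causal genes, and evaluation
    statistics (type I error, true- and false-positive proportions, ROC
    curves and AUC, per-test gene universes, Bonferroni thresholds) for
    comparing the tests under different genetic architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
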