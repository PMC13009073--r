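Package: ThyroMetab
Title: Serum Metabolome and Urinary Endocrine-Disruptor Analysis for
    Feline Hyperthyroidism Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested implementation of the statistical pipeline used in
    case-control untargeted-metabolomics studies of feline hyperthyroidism:
    instrument-blank feature filtering, mTIC normalization, log(value + 1)
    transform and Pareto scaling; per-feature one-way ANOVA with
    Benjamini-Hochberg FDR and geometric-mean fold changes; pathway
    over-representation by two-sided Fisher's exact tests; weighted
    sub-network analysis (signed soft-power adjacency, topological overlap
    dissimilarity, Ward modules, module eigenmetabolites, and
    eigenmetabolite-outcome association by Pearson correlation and logistic
    regression); PCA with loading clustering and PLS-DA with VIP scores; and
    targeted urinary endocrine-disruptor processing (LOQ/sqrt(2) imputation,
    creatinine adjustment, molar-sum exposure indices). A synthetic-data
    module generates cohorts, block-correlated metabolomes, blank profiles
    and censored EDC panels with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
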