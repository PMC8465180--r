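Package: degconcord
Title: Cross-Species Concordance Analysis of Differentially Expressed Genes
Version: 0.1.0
Authors@R:
    person("degconcord", "maintainers", email = "maintainers@degconcord.org",
           role = c("aut", "cre"))
Description: Pairs homologous differentially expressed genes (DEGs) between a
    focal domestication study and published domestic-versus-wild datasets,
    classifies the pairs by homology multiplicity, decomposes paired log2 fold
    changes into a shared domestication component (PC1) and a variation
    component (PC2) by two-variable principal component analysis, and runs the
    supporting exact small-sample statistics: Fisher's exact test and
    uncorrected Pearson chi-square on 2x2 tables, one-sided binomial sign
    tests, a Pearson/Spearman/Kendall/Goodman-Kruskal correlation suite, an
    exact Mann-Whitney U test, and two-sample Z comparisons for qPCR
    verification. Includes curated reference tables from a rat domestication
    transcriptome study, a mapping of animal DEG divergence directions onto
    human reproductive-potential effect annotations, and synthetic-data
    generators for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
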