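# degconcord

Cross-species concordance analysis of differentially expressed genes (DEGs).

`degconcord` is for transcriptomics researchers who want to ask, at desk
scale, whether the DEGs of a domestication experiment agree with published
domestic-versus-wild DEG tables from other species — and to split that
agreement into a shared "domestication" signal and a residual
intra-/interspecific variation signal. It was built around a rat
domestication study (tame versus aggressive hypothalamus, 46 DEGs) compared
against 14 published datasets (dogs/wolves, foxes, guinea pigs/cavy,
rabbits, pigs/boars, chicken), whose printed tables ship with the package as
checksummed fixtures.

## The statistic at the core

Each homologous DEG pair contributes a point (x, y): the focal and the
comparison log2 fold change (domesticated group in the numerator). A
two-variable PCA of these points gives

    PC1 fraction = (1 + |r|) / 2        (correlation convention)

where r is the Pearson correlation of the paired log2 values: PC1 is the
sign-conserving "common domestication" axis, PC2 the sign-reversing
variation axis. Around this sit

* curated symbol-level homology pairing and multiplicity classes
  (multi-supported orthologs / single orthologs / paralog support),
* exact 2x2 statistics with the conventions the published numbers pin down
  (uncorrected Pearson chi-square, one-sided Fisher exact test,
  majority-direction exact binomial),
* a Pearson / Spearman / Kendall tau-b / Goodman–Kruskal gamma correlation
  suite, an exact Mann–Whitney U test and a SEM-scaled Z comparison for
  qPCR verification,
* a mapping of DEG divergence directions onto human
  reproductive-potential effect annotations, and
* synthetic-data generators for parameter-recovery tests.

## Worked example

```r
library(degconcord)

pairs <- classify_pairs(pair_homologs(load_fixture("table4"),
                                      table6_comparison_degs(),
                                      load_fixture("maps")))
table(pairs$multiplicity_class)
#>  ORTHOLOG_MULTI ORTHOLOG_SINGLE PARALOG_SUPPORT
#>               7               7              40
```

All 54 published pairs are recovered: 7 orthologous pairs supported by
other homologs, 7 stand-alone orthologous pairs, 40 paralog-support pairs.

```r
conc <- concordance_analysis(pairs)
conc$table
#>                 same_sign opposite_sign
#> ORTHOLOG_MULTI          7             0
#> ORTHOLOG_SINGLE         2             5
conc$chi2
#> Pearson chi-square (2x2) (two-sided): statistic = 7.778, p = 0.005289
conc$fisher
#> Fisher exact test (2x2) (one-sided): statistic = 7, p = 0.01049
```

Multi-supported orthologs always keep the fold-change sign; single
orthologs mostly reverse it, and the difference is significant.

```r
res <- pca2(pairs)
sprintf("PC1: %.1f%%  PC2: %.1f%%", 100 * res$var_fraction_pc1,
        100 * res$var_fraction_pc2)
#> "PC1: 67.5%  PC2: 32.5%"
```

About two-thirds of the paired fold-change variance lies on the common
domestication axis, one-third on the variation axis.

```r
t5 <- load_fixture("table5")
v <- verify_deg(t5[t5$gene == "Ascl3", ], rnaseq_log2 = 3.99)
sprintf("qPCR log2 = %.2f, MW p = %.3g, sign agreement: %s",
        v$qpcr_log2, v$mann_whitney$p_value, v$sign_agreement)
#> "qPCR log2 = 2.95, MW p = 0.000155, sign agreement: TRUE"
```

The strongest DEG verifies on the independent qPCR animals: the 8-vs-8
groups separate completely (exact two-sided p = 2/12870).

```r
t8 <- load_fixture("table8")
h <- build_reproductive_table(human_divergence_calls(t8$animal, t8$human))
h$table
#>          decreased increased
#> domestic        13         1
#> wild             7         7
h$chi2
#> Pearson chi-square (2x2) (two-sided): statistic = 6.3, p = 0.01207
```

Mapped through human effect annotations, 13 of 14 domestic-side divergence
calls point to decreased human reproductive potential, while the wild side
splits evenly — the published contingency, reproduced.

## Command line

```sh
Rscript inst/cli/degconcord-cli.R run --out-dir out/       # full pipeline
Rscript inst/cli/degconcord-cli.R table2x2 --counts 7,0,2,5
Rscript inst/cli/degconcord-cli.R simulate pairs --n 54 --common-fraction 0.7 --seed 1
```

(after installation the script lives at `system.file("cli",
"degconcord-cli.R", package = "degconcord")`).

## Scope

The package consumes published DEG tables; read-level RNA-Seq processing
(QC, alignment, counting, DE calling) and primer design are out of scope,
and orthology is curated symbol matching, not sequence inference. The
bundled raw-data accession of the originating experiment (NCBI SRA
PRJNA668014) is documentation only and is never downloaded.
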