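---
title: "Methods: cross-species DEG concordance and its decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species DEG concordance and its decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degconcord)
```

## The question and the model

Domestication experiments repeatedly find genes whose expression differs
between a domesticated line and its wild congener. `degconcord` asks a
comparative question: when a differentially expressed gene (DEG) of a focal
domestication experiment (tame versus aggressive rats, hypothalamus) has a
homologous DEG in an independent domestic-versus-wild dataset (dogs/wolves,
tame/aggressive foxes, guinea pigs/cavy, domestic/wild rabbits, pigs/boars,
domestic/wild chicken), do the two log2 fold changes agree in sign and
magnitude?

Each homologous pair contributes a point $(x_i, y_i)$, where $x_i$ is the
focal log2 fold change (tame over aggressive) and $y_i$ the comparison
study's log2 fold change (domestic over wild). The two-variable principal
component analysis of these points splits their variance into

* **PC1**, the diagonal "common domestication" axis along which
  sign-conserving pairs lie, and
* **PC2**, the anti-diagonal axis capturing pairs that reverse sign between
  species or tissues — intra- and interspecific variation.

For two standardized variables the decomposition is fully determined by the
Pearson correlation $r$: the correlation matrix has eigenvalues $1 \pm |r|$,
so the PC1 variance fraction is exactly $(1+|r|)/2$. `pca2()` performs the
eigen-decomposition (correlation or covariance convention) and
`pc1_fraction_closed_form()` is its analytic twin; the package tests hold
the two to within $10^{-12}$.

## Homologous-pair compilation and multiplicity

Pairing is symbol-level curation, not sequence comparison (`pair_homologs()`):

* symbols are normalized (`normalize_symbol()`: markup stripped, lowercased,
  typographic minus mapped to ASCII, curated aliases applied — e.g.
  `Mre11` is recorded as `mre11a`);
* identical canonical symbols, or an explicit curated entry
  (e.g. `hbb-b1 ~ hbbl`), give an **orthologous** pair;
* a shared curated family root (e.g. `hbb-b1`, `hba1`, `hbz1` → `hb`;
  `pla2g2c`, `pla2g4c` → `pla`) gives a **paralog-support** pair.

A shared-prefix heuristic (leading alphabetic prefix of length ≥ 2) can pair
symbols that have no curated family entry; any curated entry suppresses the
heuristic for that symbol, because prefixes alone would wrongly merge, for
example, `Shox2` with `Sh3bgr` or `Plac8` with the phospholipase family. The
curated map therefore contains a few self-root "blocking" entries. Strict
runs (`use_fallback = FALSE`) use curation only; on the bundled tables both
modes give the identical 54 pairs.

`classify_pairs()` counts, per focal gene, the total number of pairs $k$ it
participates in, pooling comparison species and tissues (two tissue rows of
the same gene corroborate each other). Orthologous pairs with $k \ge 2$
become `ORTHOLOG_MULTI`, orthologous pairs with $k = 1$ `ORTHOLOG_SINGLE`,
and the rest stay `PARALOG_SUPPORT`. On the bundled tables this yields
7 multi-supported orthologous pairs (all sign-concordant), 7 single
orthologous pairs (5 of 7 sign-discordant) and 40 paralog-support pairs.

## Statistical conventions

The printed statistics this package re-derives pin down several conventions,
which are therefore the defaults and are echoed into every report:

* **Pearson chi-square without Yates correction** (`chi2_2x2()`): only the
  uncorrected statistic reproduces both published values (7.78 for the
  sign-concordance table `[[7,0],[2,5]]` and 6.30 for the human mapping
  table `[[13,1],[7,7]]`). The correction is available by flag.
* **Fisher's exact test, one-sided** (`fisher_exact_2x2()`), tail chosen in
  the direction of the observed association; the published bounds (≤ 0.05)
  match the one-sided values. Two-sided (probability-ordering rule) by flag.
* **Exact binomial sign test, one-sided in the majority direction**
  (`binomial_sign_test()`): upper tail including the observed count, so a
  7/7 tie in a 14-call row yields $P(X \ge 7) = 0.60$. At the small row
  sizes used here (7 and 14) the discreteness makes the test conservative;
  at much larger $n$ its data-driven direction choice behaves like a
  two-sided test, which is why the type-I simulation in the test suite runs
  at the sizes the analysis actually uses.
* **Kendall's tau is tau-b** (tie-corrected) and **Goodman–Kruskal gamma**
  excludes tied pairs, so $|\tau| \le |\gamma|$ always; this inequality is a
  property test.
* **Mann–Whitney U** (`mann_whitney_u()`): exact p-values by complete
  enumeration of group reassignments (conditioning on the observed pooled
  values) when both groups have ≤ 10 observations and no cross-group ties;
  otherwise the tie-corrected normal approximation without continuity
  correction. An 8-versus-8 complete separation gives the exact two-sided
  floor $2/\binom{16}{8} = 2/12870$.
* **"Z-test" of group means** (`z_test_two_sample()`):
  $Z = (m_1 - m_2)/\sqrt{\mathrm{SEM}_1^2 + \mathrm{SEM}_2^2}$. The source
  literature's label for this comparison is ambiguous; the r-to-z reading is
  provided separately as `fisher_z_correlation()`.

## qPCR verification

`aggregate_group()` averages per-animal relative expression (mean ± SEM,
$n-1$ standard deviation; technical-replicate variance is not propagated
because only per-animal summaries are consumed). Below-detection animals
("ND") are **excluded from means** — this reproduces the published group
means, including the 0.01 mean of the low group of the defensin gene — but
**imputed at the detection limit (0.01) for hypothesis tests**, keeping both
groups at full size, which is conservative for rank tests. Both policies are
configurable. `verify_deg()` combines the rank test, the Z comparison, the
qPCR log2 ratio and the sign agreement with the RNA-Seq estimate;
`crossplatform_correlation()` adds the regression of one platform on the
other with its 95% confidence band.

The published TOTAL "±" values are *not* reproducible as SEMs of the printed
per-animal means (e.g. 0.52 printed versus 0.21 recomputed for the tame
group of the strongest gene); whatever aggregation produced them is
unstated, so only the means are asserted.

## Human reproductive-potential mapping

Each animal DEG row carries a curated human ortholog whose annotation states
what an expression *deficit* and an *excess* do to human reproductive
potential. `assign_divergence_sides()` reads the fold-change sign (domestic
group in the numerator): negative means the domestic side diverged into
deficit and the wild side into excess; `map_to_human_effect()` then looks up
the annotated effect for each side, and `build_reproductive_table()` tallies
the 14 calls into the 2x2 of divergence side × mapped effect and runs the
chi-square/Fisher/binomial battery. The annotations are data, not
computation; updating them against the literature is out of scope.

## Synthetic data: what it emulates and what it does not

`simulate_paired_log2()` generates the stated world of the paired analysis:
per gene a sign and two log-uniform magnitudes on $[0.25, 7.5]$ (bracketing
the smallest and largest absolute log2 values in the bundled tables, 0.25
and 7.34; log-uniform because no distributional claim is available and it
spreads decades evenly), a common-domestication indicator with probability
$f$ (default 0.7, near the bundled tables' concordant share), sign
re-randomization for the rest, and additive Gaussian noise (default SD 0.5,
a mid-range study-to-study scatter chosen once). The expected
sign-concordant share is $f + (1-f)/2$, and the recovered PC1 fraction is
monotone in $f$ — both are property tests. One seed drives one stream with
seven uniforms per gene at fixed offsets, so a shorter run is a prefix of a
longer one.

`simulate_qpcr()` draws per-animal values log-normally around group means
(moment-matched, CV default 0.5 as in the bundled per-animal scatter) with
below-detection censoring at 0.01 and the 8-versus-8 design.

The generators emulate magnitudes, sign structure, censoring and group
separation; they do **not** emulate count-level noise, normalization
artifacts, correlated genes, or shared-animal dependence between genes. A
green parameter-recovery test therefore establishes that the pipeline
recovers the generative sign structure, not that real data meet these
assumptions.

## Numerical choices and degenerate inputs

* Zero fold changes have no sign: they are rejected by the divergence-side
  assignment and dropped (with a warning) from sign-concordance counts.
* A zero margin makes the chi-square expected counts degenerate; the
  concordance analyses omit the statistic with a warning rather than fail.
* Eigenvector sign is fixed by a non-negative focal loading on each
  component.
* Rank-test p-values are floored at the smallest positive double so they
  remain in $(0, 1]$ even for perfect association.
* Two-sided Fisher uses the standard probability-ordering rule with a
  $10^{-7}$ relative tolerance.

## Design decisions that were genuinely open

* **PCA convention.** The published split ("two-thirds / one-third",
  printed 67%/33%) does not state the standardization. Both conventions are
  implemented; on the 54 bundled pairs they give PC1 fractions of 0.67540
  and 0.67559 — numerically indistinguishable here, both rounding to 68%.
  Neither reproduces the printed integer 67 under nearest-integer rounding
  (67 appears to be a truncation or a loose "two-thirds"); the package
  keeps the correlation convention as the default, reports the computed
  value, and the corresponding acceptance assertion is deliberately left
  failing rather than tuned.
* **Scatter-plot stratum membership.** The published stratified correlation
  panels include paralog companions of multi-pair genes — including a gene
  with seven paralog pairs and no orthologous pair. The inclusive default
  therefore strata by the focal gene's total pair count (≥ 2 versus 1); a
  strict mode restricts to orthologous pairs only (7 and 7). The two modes
  bracket the published panels' unstated membership; both give the
  published signs (positive multi-stratum, negative single-stratum
  correlation).
* **Single-ortholog enumeration.** The source text lists six row numbers
  for the seven named single orthologs; the seven-gene reading (rows 6, 9,
  28, 34, 51, 52, 53) is used, consistent with its own seven-pair count.

## Known limitations

* Orthology is curated symbol matching; no sequence, synteny or phylogeny
  support. The curated maps encode one study's judgment calls.
* Read-level processing (QC, alignment, counting, DE calling) is upstream
  and out of scope; the package consumes published DEG tables.
* The human effect annotations cover the three gene families of the bundled
  mapping; applying the mapping to new genes requires new curation.
* The exact Mann–Whitney path enumerates $\binom{n_1+n_2}{n_1}$
  assignments; above 10 per group it switches to the normal approximation.
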