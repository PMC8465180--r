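#' Two-variable principal component analysis of paired log2 fold changes
#'
#' Eigen-decomposition of the 2x2 correlation (default) or covariance matrix
#' of the paired values. Variance fractions are the eigenvalues divided by
#' their sum; PC1 is the larger-eigenvalue axis and its loading on the focal
#' coordinate is fixed non-negative (eigenvectors are sign-ambiguous). In
#' correlation mode the PC1 fraction obeys the closed form `(1 + |r|) / 2`
#' for two standardized variables, see [pc1_fraction_closed_form()].
#'
#' @param pairs A two-column matrix/data frame of (focal log2fc, comparison
#'   log2fc), or a `homolog_pairs` data frame (columns `focal_log2fc`,
#'   `comp_log2fc` are used).
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @return An object of class `pca2_result`: list with `var_fraction_pc1`,
#'   `var_fraction_pc2`, `loadings` (2x2 orthonormal, columns PC1, PC2),
#'   `mode`, `n`.
#' @examples
#' res <- pca2(classify_pairs(pair_homologs(load_fixture("table4"),
#'             table6_comparison_degs(), load_fixture("maps"))))
#' round(100 * res$var_fraction_pc1)  # 68 (printed as "two-thirds", 67)
#' @export
pca2 <- function(pairs, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  xy <- .pair_coords(pairs)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (mode == "correlation" && (sd(xy[, 1]) == 0 || sd(xy[, 2]) == 0))
    stop("constant coordinate: correlation-mode PCA undefined", call. = FALSE)
  m <- if (mode == "correlation") cor(xy) else cov(xy)
  e <- eigen(m, symmetric = TRUE)
  fr <- e$values / sum(e$values)
  load <- e$vectors
  for (j in 1:2) if (load[1, j] < 0) load[, j] <- -load[, j]
  dimnames(load) <- list(c("focal", "comparison"), c("PC1", "PC2"))
  structure(list(var_fraction_pc1 = fr[1], var_fraction_pc2 = fr[2],
                 loadings = load, mode = mode, n = n),
            class = "pca2_result")
}

.pair_coords <- function(pairs) {
  if (is.data.frame(pairs) &&
      all(c("focal_log2fc", "comp_log2fc") %in% names(pairs)))
    return(cbind(pairs$focal_log2fc, pairs$comp_log2fc))
  m <- as.matrix(pairs)
  if (ncol(m) != 2) stop("expected two coordinates per pair", call. = FALSE)
  m
}

#' Closed-form PC1 variance fraction for two standardized variables
#'
#' For a two-variable correlation-mode PCA the eigenvalues of the correlation
#' matrix are `1 + |r|` and `1 - |r|`, so the PC1 variance fraction is
#' `(1 + |r|) / 2`. This is the analytic twin of [pca2()] used for
#' verification.
#'
#' @param r Pearson correlation of the two coordinates, in `[-1, 1]`.
#' @return The PC1 variance fraction.
#' @export
pc1_fraction_closed_form <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  (1 + abs(r)) / 2
}

#' Sign-concordance contingency analysis of classified homologous pairs
#'
#' Builds the 2x2 table of homology multiplicity class (rows: multi-supported
#' orthologs, single orthologs) by log2 sign concordance (columns: same sign,
#' opposite sign); only orthologous pairs enter the table. Pairs with a zero
#' fold change on either side have an undefined sign and are dropped with a
#' warning. Runs Fisher's exact test (one-sided), the uncorrected Pearson
#' chi-square (omitted with a warning when a margin is zero), and the
#' majority-direction binomial sign test per row.
#'
#' @param classified_pairs Output of [classify_pairs()].
#' @return A list of class `concordance_result`: `table` ([xtab2x2()]),
#'   `fisher`, `chi2`, `binomial_multi`, `binomial_single`.
#' @export
concordance_analysis <- function(classified_pairs) {
  p <- classified_pairs
  stopifnot(all(c("multiplicity_class", "focal_log2fc", "comp_log2fc")
                %in% names(p)))
  orth <- p[p$multiplicity_class %in% c("ORTHOLOG_MULTI", "ORTHOLOG_SINGLE"), ]
  if (!nrow(orth)) stop("no orthologous pairs", call. = FALSE)
  zero <- orth$focal_log2fc == 0 | orth$comp_log2fc == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with zero log2fc dropped (undefined sign)")
    orth <- orth[!zero, ]
  }
  same <- orth$focal_log2fc * orth$comp_log2fc > 0
  multi <- orth$multiplicity_class == "ORTHOLOG_MULTI"
  tab <- xtab2x2(sum(multi & same), sum(multi & !same),
                 sum(!multi & same), sum(!multi & !same),
                 row_labels = c("ORTHOLOG_MULTI", "ORTHOLOG_SINGLE"),
                 col_labels = c("same_sign", "opposite_sign"))
  chi2 <- tryCatch(chi2_2x2(tab), error = function(e) {
    warning("chi-square omitted: ", conditionMessage(e)); NULL
  })
  row_binom <- function(counts) {
    k <- max(counts); n <- sum(counts)
    if (n == 0) return(NULL)
    binomial_sign_test(k, n)
  }
  structure(list(table = tab,
                 fisher = fisher_exact_2x2(tab, sided = "one"),
                 chi2 = chi2,
                 binomial_multi = row_binom(tab[1, ]),
                 binomial_single = row_binom(tab[2, ])),
            class = "concordance_result")
}

#' Stratified correlation analysis of classified homologous pairs
#'
#' Runs the full [correlation_suite()] separately on the "multi" and
#' "single" strata of (focal log2fc, comparison log2fc) pairs. In
#' `"inclusive"` mode (default) the multi stratum contains every pair whose
#' focal gene participates in two or more pairs (orthologous or
#' paralog-support), and the single stratum every pair whose focal gene has
#' exactly one pair; this follows the published scatter plots, which place
#' paralog companions (including genes with no orthologous pair at all) with
#' the multi-supported orthologs. `"strict"` mode restricts each stratum to
#' orthologous pairs only.
#'
#' @param classified_pairs Output of [classify_pairs()].
#' @param membership `"inclusive"` or `"strict"`.
#' @return A list with elements `multi` and `single`, each a
#'   `correlation_suite`, plus `membership` and per-stratum sizes.
#' @export
stratified_correlations <- function(classified_pairs,
                                    membership = c("inclusive", "strict")) {
  membership <- match.arg(membership)
  p <- classified_pairs
  stopifnot(all(c("multiplicity_class", "focal_symbol") %in% names(p)))
  if (membership == "strict") {
    in_multi <- p$multiplicity_class == "ORTHOLOG_MULTI"
    in_single <- p$multiplicity_class == "ORTHOLOG_SINGLE"
  } else {
    k <- table(p$focal_symbol)
    kk <- as.integer(k[p$focal_symbol])
    in_multi <- kk >= 2L
    in_single <- kk == 1L
  }
  run <- function(sel, label) {
    if (sum(sel) < 3)
      stop("stratum '", label, "' has fewer than 3 pairs", call. = FALSE)
    correlation_suite(p$focal_log2fc[sel], p$comp_log2fc[sel])
  }
  list(multi = run(in_multi, "multi"),
       single = run(in_single, "single"),
       membership = membership,
       n_multi = sum(in_multi), n_single = sum(in_single))
}
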