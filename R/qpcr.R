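#' Aggregate per-animal qPCR relative expression into a group summary
#'
#' Computes the group mean `m0` and its standard error over per-animal
#' relative expression values for one gene and one group. Values below the
#' detection limit (`nd_flag`) are handled per `nd_policy`: `"exclude"`
#' drops them (this matches the published group means, whose not-detected
#' animals do not enter the average) and `"impute"` substitutes the
#' detection limit, keeping the group at full size for rank tests.
#'
#' The SEM is the n-1 sample standard deviation of the per-animal means
#' divided by `sqrt(n_used)`; technical-replicate variance is not propagated
#' (only per-animal summaries are consumed).
#'
#' @param samples Data frame with columns `gene`, `group`, `rel_expr` and
#'   `nd_flag` (as from `load_fixture("table5")` or [simulate_qpcr()]), all
#'   rows belonging to one gene and one group.
#' @param nd_policy `"exclude"` (default) or `"impute"`.
#' @param detection_limit Value substituted under `"impute"`.
#' @return A list of class `qpcr_group_summary`: `gene`, `group`, `m0`,
#'   `sem`, `n_used`, `n_nd`.
#' @examples
#' t5 <- load_fixture("table5")
#' ascl3_t <- t5[t5$gene == "Ascl3" & t5$group == "tame", ]
#' round(aggregate_group(ascl3_t)$m0, 2)  # 2.04
#' @export
aggregate_group <- function(samples, nd_policy = c("exclude", "impute"),
                            detection_limit = 0.01) {
  nd_policy <- match.arg(nd_policy)
  stopifnot(is.data.frame(samples),
            all(c("gene", "group", "rel_expr") %in% names(samples)))
  if (length(unique(samples$gene)) != 1 || length(unique(samples$group)) != 1)
    stop("samples must belong to a single gene and group", call. = FALSE)
  nd <- if ("nd_flag" %in% names(samples)) samples$nd_flag else
    is.na(samples$rel_expr)
  v <- samples$rel_expr
  if (nd_policy == "impute") {
    v[nd] <- detection_limit
  } else {
    v <- v[!nd]
  }
  if (!length(v)) stop("no detected animals in group", call. = FALSE)
  structure(list(gene = samples$gene[1], group = samples$group[1],
                 m0 = mean(v),
                 sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
                 n_used = length(v), n_nd = sum(nd)),
            class = "qpcr_group_summary")
}

#' log2 expression ratio of two group summaries
#'
#' `log2(high$m0 / low$m0)`, the qPCR analogue of the RNA-Seq log2 fold
#' change (numerator = tame/domestic group).
#'
#' @param high,low `qpcr_group_summary` objects (numerator, denominator).
#' @return The log2 ratio.
#' @export
group_log2_ratio <- function(high, low) {
  stopifnot(inherits(high, "qpcr_group_summary"),
            inherits(low, "qpcr_group_summary"))
  if (high$m0 <= 0 || low$m0 <= 0)
    stop("group means must be positive", call. = FALSE)
  log2(high$m0 / low$m0)
}

#' Cross-platform verification of one DEG
#'
#' Compares the tame and aggressive qPCR groups of a gene by the
#' Mann-Whitney U test and the SEM-scaled two-sample Z test, computes the
#' qPCR log2 ratio, and reports sign agreement with the RNA-Seq fold change
#' and significance flags at `alpha`. For the rank and Z tests, not-detected
#' animals are imputed at the detection limit (keeping groups at full size);
#' group means use the exclude policy, matching the published summaries.
#'
#' @param gene_samples Data frame of one gene's per-animal rows (both
#'   groups), columns as in `load_fixture("table5")`.
#' @param rnaseq_log2 The RNA-Seq log2 fold change of the gene (tame vs
#'   aggressive).
#' @param alpha Significance level for the flags.
#' @param detection_limit Imputation value for not-detected animals.
#' @return A list of class `deg_verification`: `gene`, `mann_whitney`,
#'   `z_test`, `qpcr_log2`, `rnaseq_log2`, `sign_agreement`, `significant`
#'   (both tests below `alpha`).
#' @export
verify_deg <- function(gene_samples, rnaseq_log2, alpha = 0.05,
                       detection_limit = 0.01) {
  stopifnot(is.data.frame(gene_samples))
  groups <- unique(gene_samples$group)
  if (length(groups) != 2)
    stop("need exactly two groups, got: ", paste(groups, collapse = ", "),
         call. = FALSE)
  hi_lab <- if ("tame" %in% groups) "tame" else groups[1]
  lo_lab <- setdiff(groups, hi_lab)[1]
  hi <- gene_samples[gene_samples$group == hi_lab, ]
  lo <- gene_samples[gene_samples$group == lo_lab, ]

  imputed <- function(g) {
    v <- g$rel_expr
    nd <- if ("nd_flag" %in% names(g)) g$nd_flag else is.na(v)
    v[nd] <- detection_limit
    v
  }
  mw <- mann_whitney_u(imputed(lo), imputed(hi))
  s_hi <- aggregate_group(hi, nd_policy = "impute",
                          detection_limit = detection_limit)
  s_lo <- aggregate_group(lo, nd_policy = "impute",
                          detection_limit = detection_limit)
  zt <- z_test_two_sample(s_hi$m0, max(s_hi$sem, .Machine$double.eps),
                          s_lo$m0, max(s_lo$sem, .Machine$double.eps))
  m_hi <- aggregate_group(hi, nd_policy = "exclude")
  m_lo <- aggregate_group(lo, nd_policy = "exclude")
  ql2 <- group_log2_ratio(m_hi, m_lo)
  structure(list(gene = gene_samples$gene[1],
                 mann_whitney = mw, z_test = zt,
                 qpcr_log2 = ql2, rnaseq_log2 = rnaseq_log2,
                 sign_agreement = sign(ql2) == sign(rnaseq_log2),
                 significant = mw$p_value < alpha & zt$p_value < alpha),
            class = "deg_verification")
}

#' Correlation of platform log2 fold changes (RNA-Seq vs qPCR)
#'
#' Full [correlation_suite()] on the paired platform estimates, plus the
#' linear regression of qPCR on RNA-Seq with the half-width of the 95%
#' confidence band at each point.
#'
#' @param points Data frame or matrix with two columns: RNA-Seq log2 and
#'   qPCR log2 (in that order), `n >= 3` rows.
#' @return A list: `suite` (`correlation_suite`), `slope`, `intercept`,
#'   `conf_halfwidth` (vector, one per point).
#' @export
crossplatform_correlation <- function(points) {
  m <- as.matrix(points)
  if (ncol(m) != 2 || nrow(m) < 3)
    stop("need an n x 2 matrix of points, n >= 3", call. = FALSE)
  d <- data.frame(x = m[, 1], y = m[, 2])
  fit <- lm(y ~ x, data = d)
  ci <- predict(fit, interval = "confidence", level = 0.95)
  list(suite = correlation_suite(d$x, d$y),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       conf_halfwidth = unname((ci[, "upr"] - ci[, "lwr"]) / 2))
}
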