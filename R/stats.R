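#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer counts; row 1 is `[a, b]`, row 2 is
#'   `[c, d]`.
#' @param row_labels,col_labels Length-2 character vectors.
#' @return A classed 2x2 integer matrix (`xtab2x2`).
#' @export
xtab2x2 <- function(a, b, c, d,
                    row_labels = c("row1", "row2"),
                    col_labels = c("col1", "col2")) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE,
              dimnames = list(row_labels, col_labels))
  class(m) <- c("xtab2x2", class(m))
  m
}

#' @export
print.xtab2x2 <- function(x, ...) {
  m <- unclass(x)
  print(m, ...)
  invisible(x)
}

.as_2x2 <- function(t) {
  m <- unclass(t)
  if (!is.matrix(m) || !all(dim(m) == 2L))
    stop("expected a 2x2 table", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

.test_result <- function(statistic, p_value, sided, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 sided = sided, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, " (", x$sided, "-sided): statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The one-sided p-value is the
#' tail in the direction of the observed association: the upper tail
#' `P(A >= a)` when cell `a` is at or above its expectation under
#' independence, the lower tail otherwise. The two-sided p-value sums the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (with a 1e-7 relative
#' tolerance).
#'
#' @param t A 2x2 table ([xtab2x2()] or plain matrix).
#' @param sided `"one"` (default) or `"two"`.
#' @return A `test_result`; `statistic` is the observed cell `a`.
#' @examples
#' fisher_exact_2x2(xtab2x2(7, 0, 2, 5))$p_value  # 0.01049
#' @export
fisher_exact_2x2 <- function(t, sided = c("one", "two")) {
  sided <- match.arg(sided)
  m <- .as_2x2(t)
  if (sum(m) == 0) stop("all-zero table", call. = FALSE)
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  if (sided == "one") {
    expected_a <- r1 * c1 / n
    p <- if (a >= expected_a) sum(probs[support >= a]) else
      sum(probs[support <= a])
  } else {
    p_obs <- probs[support == a]
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  .test_result(a, min(p, 1), sided, "Fisher exact test (2x2)")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected by default: only the uncorrected statistic reproduces the
#' published values this package re-derives (7.78 and 6.30). Yates continuity
#' correction is available via `continuity_correction`.
#'
#' @param t A 2x2 table.
#' @param continuity_correction Subtract 0.5 from each `|obs - exp|` if
#'   `TRUE`.
#' @return A `test_result` with the chi-square statistic (1 df, two-sided).
#' @examples
#' chi2_2x2(xtab2x2(7, 0, 2, 5))$statistic  # 7.7778
#' @export
chi2_2x2 <- function(t, continuity_correction = FALSE) {
  m <- .as_2x2(t)
  if (sum(m) == 0) stop("all-zero table", call. = FALSE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(e == 0))
    stop("zero margin: expected count of zero", call. = FALSE)
  d <- abs(m - e)
  if (continuity_correction) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / e)
  .test_result(stat, pchisq(stat, df = 1, lower.tail = FALSE), "two",
               paste0("Pearson chi-square (2x2",
                      if (continuity_correction) ", Yates-corrected", ")"))
}

#' Exact binomial sign test
#'
#' One-sided in the direction of the observed majority: for `k >= n * p0` the
#' upper tail `P(X >= k)` (inclusive of the observed count, so a tie at
#' `k = n/2` under `p0 = 0.5` yields the upper-tail probability including
#' `k`), otherwise the lower tail `P(X <= k)`. Two-sided doubles the
#' one-sided value, capped at 1.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param sided `"one"` (default) or `"two"`.
#' @return A `test_result`; `statistic` is `k`.
#' @examples
#' binomial_sign_test(5, 7)$p_value   # 0.2266
#' binomial_sign_test(7, 7)$p_value   # 1/128
#' @export
binomial_sign_test <- function(k, n, p0 = 0.5, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("require integers 0 <= k <= n, n >= 1", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  p1 <- if (k >= n * p0) sum(dbinom(k:n, n, p0)) else sum(dbinom(0:k, n, p0))
  p <- if (sided == "one") p1 else min(1, 2 * p1)
  .test_result(k, min(p, 1), sided, "exact binomial sign test")
}

# Concordant/discordant pair counts and tie sums for rank statistics.
.concordance_counts <- function(x, y) {
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  list(C = sum(s > 0), D = sum(s < 0),
       tx = sum(dx[up] == 0), ty = sum(dy[up] == 0))
}

#' Correlation suite: Pearson, Spearman, Kendall tau-b, Goodman-Kruskal gamma
#'
#' Computes the four association coefficients reported together throughout
#' this package, with their significance levels: Pearson's r and Spearman's
#' rho with t-approximation p-values, Kendall's tau-b (tie-corrected) with a
#' normal-approximation p-value, and the Goodman-Kruskal gamma
#' `(C - D) / (C + D)` over concordant/discordant pairs excluding ties, with
#' its asymptotic-standard-error normal p-value. P-values are two-sided and
#' floored at the smallest positive double so they stay in (0, 1].
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return An object of class `correlation_suite`: list with `r`, `rho`,
#'   `tau`, `gamma`, `p_r`, `p_rho`, `p_tau`, `p_gamma`, `n`.
#' @examples
#' s <- correlation_suite(1:6, (1:6)^2)
#' s$rho; s$gamma  # 1, 1
#' @export
correlation_suite <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: Pearson correlation undefined", call. = FALSE)

  t_p <- function(coef) {
    if (abs(coef) >= 1) return(.Machine$double.xmin)
    tt <- coef * sqrt((n - 2) / (1 - coef^2))
    max(2 * pt(-abs(tt), df = n - 2), .Machine$double.xmin)
  }
  r <- cor(x, y)
  rho <- cor(rank(x), rank(y))

  cc <- .concordance_counts(x, y)
  n0 <- n * (n - 1) / 2
  tau <- (cc$C - cc$D) / sqrt((n0 - cc$tx) * (n0 - cc$ty))
  if (cc$C + cc$D == 0)
    stop("no untied pairs: gamma undefined", call. = FALSE)
  gam <- (cc$C - cc$D) / (cc$C + cc$D)

  # Kendall: normal approximation under H0 (no-tie variance)
  z_tau <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  p_tau <- max(2 * pnorm(-abs(z_tau)), .Machine$double.xmin)
  # Gamma: asymptotic z = gamma * sqrt((C + D) / (n (1 - gamma^2)))
  p_gam <- if (abs(gam) >= 1) .Machine$double.xmin else
    max(2 * pnorm(-abs(gam * sqrt((cc$C + cc$D) / (n * (1 - gam^2))))),
        .Machine$double.xmin)

  structure(list(r = r, rho = rho, tau = tau, gamma = gam,
                 p_r = t_p(r), p_rho = t_p(rho), p_tau = p_tau,
                 p_gamma = p_gam, n = n),
            class = "correlation_suite")
}

#' @export
print.correlation_suite <- function(x, ...) {
  cat(sprintf("n = %d\n  r     = %6.3f (p = %.3g)\n  rho   = %6.3f (p = %.3g)\n  tau-b = %6.3f (p = %.3g)\n  gamma = %6.3f (p = %.3g)\n",
              x$n, x$r, x$p_r, x$rho, x$p_rho, x$tau, x$p_tau,
              x$gamma, x$p_gamma))
  invisible(x)
}

# Exact permutation distribution of U = #{x_i > y_j} (+ 0.5 per tie),
# conditioning on the observed pooled values. Returns sorted U values with
# probabilities.
.u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

.u_exact_pvalue <- function(x, y) {
  n1 <- length(x)
  z <- c(x, y)
  rk <- rank(z)                      # midranks
  idx <- combn(length(z), n1)
  # U = sum of x-ranks - n1(n1+1)/2 holds with midranks too
  usub <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  u_obs <- .u_statistic(x, y)
  tol <- 1e-9
  p_le <- mean(usub <= u_obs + tol)
  p_ge <- mean(usub >= u_obs - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When both groups have at most `exact_threshold`
#' observations and there are no ties between the groups, the p-value is
#' computed from the complete permutation distribution of U over all
#' reassignments of the pooled observations (exact). Otherwise the normal
#' approximation with tie correction is used (no continuity correction).
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_threshold Maximum per-group size for the exact enumeration.
#' @return A `test_result`; `statistic` is `U = #\{x > y\}` counting
#'   cross-group ties as 1/2.
#' @examples
#' a <- c(0.22, 0.14, 1.04, 0.11, 0.22, 0.14, 0.12, 0.12)
#' t <- c(1.05, 1.35, 2.05, 1.95, 2.35, 2.61, 2.08, 2.86)
#' mann_whitney_u(a, t)$p_value  # 2/12870
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 10L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  u <- .u_statistic(x, y)
  cross_ties <- any(outer(x, y, "=="))
  if (length(x) <= exact_threshold && length(y) <= exact_threshold &&
      !cross_ties) {
    p <- .u_exact_pvalue(x, y)
    method <- "Mann-Whitney U (exact permutation)"
  } else {
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  .test_result(u, p, "two", method)
}

#' Two-sample Z comparison of group means
#'
#' `Z = (mean1 - mean2) / sqrt(sem1^2 + sem2^2)` with a two-sided normal
#' p-value. This is the group-mean comparison applied to qPCR summaries
#' (often reported in this literature as a "Z-test"; see
#' [fisher_z_correlation()] for the correlation-coefficient reading).
#'
#' @param mean1,mean2 Group means.
#' @param sem1,sem2 Standard errors of the means (must be positive).
#' @return A `test_result`.
#' @export
z_test_two_sample <- function(mean1, sem1, mean2, sem2) {
  if (!is.finite(sem1) || !is.finite(sem2) || sem1 <= 0 || sem2 <= 0)
    stop("SEMs must be positive", call. = FALSE)
  z <- (mean1 - mean2) / sqrt(sem1^2 + sem2^2)
  .test_result(z, min(1, 2 * pnorm(-abs(z))), "two",
               "two-sample Z test of means (SEM-scaled)")
}

#' Fisher r-to-z significance of a correlation coefficient
#'
#' `z = atanh(r) * sqrt(n - 3)` with a two-sided normal p-value.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Sample size, `n >= 4`.
#' @return A `test_result`.
#' @export
fisher_z_correlation <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  z <- atanh(r) * sqrt(n - 3)
  .test_result(z, min(1, 2 * pnorm(-abs(z))), "two",
               "Fisher r-to-z correlation test")
}
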