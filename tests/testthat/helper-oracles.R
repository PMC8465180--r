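# Independent oracles used across the suite. These deliberately avoid the
# code paths (and where possible the distribution kernels) of the package
# functions they check.

# Hypergeometric probability of cell a from first principles (choose()).
hyper_prob <- function(a, r1, c1, n) {
  exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1))
}

# Brute-force Fisher exact test: enumerate every table with the observed
# margins; probabilities from choose(), not dhyper().
fisher_oracle <- function(m, sided = "one") {
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- hyper_prob(support, r1, c1, n)
  if (sided == "one") {
    if (a >= r1 * c1 / n) sum(probs[support >= a]) else
      sum(probs[support <= a])
  } else {
    sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
  }
}

# Direct binomial tail by pmf summation from choose().
binom_tail_oracle <- function(k, n, p0 = 0.5) {
  pmf <- function(i) exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0))
  if (k >= n * p0) sum(vapply(k:n, pmf, 1)) else sum(vapply(0:k, pmf, 1))
}

# Exact two-sided Mann-Whitney p for tie-free data via the closed-form
# rank-sum distribution (base R pwilcox), independent of the package's
# combinatorial enumeration.
mw_oracle_distinct <- function(x, y) {
  u <- sum(outer(x, y, ">"))
  m <- length(x); n <- length(y)
  min(1, 2 * min(pwilcox(u, m, n), 1 - pwilcox(u - 1, m, n)))
}

# Fixture-derived classified pairs, built once per test file.
fixture_pairs <- function() {
  classify_pairs(pair_homologs(load_fixture("table4"),
                               table6_comparison_degs(),
                               load_fixture("maps")))
}

# Map classified pairs back to the source row numbers of the packaged
# 54-pair table.
fixture_pair_rows <- function(pairs) {
  t6 <- load_fixture("table6")
  key <- function(f, co, ti, l) paste(tolower(f), tolower(co), ti, l)
  t6$row[match(key(pairs$focal_symbol, pairs$comp_symbol,
                   pairs$comp_tissue, pairs$comp_log2fc),
               key(t6$focal_symbol, t6$comp_symbol, t6$tissue,
                   t6$comp_log2fc))]
}
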