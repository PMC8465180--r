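test_that("fisher_exact_2x2 matches hand-derived values", {
  # P(a = 7 | margins 7,7 x 9,5) = C(9,7)/C(14,7) = 36/3432
  expect_equal(fisher_exact_2x2(xtab2x2(7, 0, 2, 5))$p_value, 36 / 3432,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(xtab2x2(1, 0, 0, 1))$p_value, 0.5)
  expect_error(fisher_exact_2x2(xtab2x2(0, 0, 0, 0)), "all-zero")
})

test_that("fisher_exact_2x2 equals brute-force margin enumeration", {
  set.seed(42)
  for (i in 1:250) {
    m <- matrix(rbinom(4, 8, 0.5), 2)
    if (sum(m) == 0) next
    t <- xtab2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    expect_equal(fisher_exact_2x2(t, "one")$p_value, fisher_oracle(m, "one"),
                 tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(t, "two")$p_value, fisher_oracle(m, "two"),
                 tolerance = 1e-10)
  }
  # and two-sided agrees with the classical conditional test
  m <- matrix(c(7, 0, 2, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(m, "two")$p_value,
               stats::fisher.test(m)$p.value, tolerance = 1e-10)
})

test_that("chi2_2x2 reproduces the published statistics without correction", {
  expect_equal(chi2_2x2(xtab2x2(7, 0, 2, 5))$statistic, 7.78,
               tolerance = 0.005)
  expect_equal(chi2_2x2(xtab2x2(13, 1, 7, 7))$statistic, 6.30,
               tolerance = 0.005)
  expect_equal(chi2_2x2(xtab2x2(5, 5, 5, 5))$statistic, 0)
  expect_error(chi2_2x2(xtab2x2(1, 1, 0, 0)), "zero margin")
  # Yates correction matches the base-R implementation
  m <- xtab2x2(12, 3, 5, 9)
  expect_equal(chi2_2x2(m, continuity_correction = TRUE)$statistic,
               unname(stats::chisq.test(unclass(m))$statistic),
               tolerance = 1e-10)
})

test_that("binomial_sign_test equals direct pmf summation", {
  expect_equal(binomial_sign_test(5, 7)$p_value, 0.2265625)
  expect_equal(binomial_sign_test(7, 7)$p_value, 1 / 128)
  expect_equal(binomial_sign_test(13, 14)$p_value, 15 / 16384)
  expect_equal(binomial_sign_test(0, 10)$p_value, binom_tail_oracle(0, 10))
  for (n in c(1, 5, 14, 29)) {
    for (k in 0:n) {
      expect_equal(binomial_sign_test(k, n)$p_value, binom_tail_oracle(k, n),
                   tolerance = 1e-12)
    }
  }
  expect_equal(binomial_sign_test(0, 5)$p_value + 0,
               binom_tail_oracle(0, 5))  # P(X <= 0) lower tail
  expect_error(binomial_sign_test(8, 7), "0 <= k <= n")
})

test_that("binomial one-sided test controls type-I error at alpha 0.05", {
  # concordance of independent signs: k ~ Binom(n, 1/2). At the per-row
  # sizes the analysis uses (7 and 14), the discrete majority-direction
  # tail is conservative; at much larger n its data-driven direction choice
  # behaves like a two-sided test and exceeds the nominal level.
  for (n in c(7, 14)) {
    pvals <- vapply(0:n, function(k) binomial_sign_test(k, n)$p_value, 1)
    set.seed(123)
    k <- rbinom(10000, n, 0.5)
    expect_lte(mean(pvals[k + 1] < 0.05), 0.06)
  }
})

test_that("correlation_suite recovers monotone and discordant structure", {
  s <- correlation_suite(1:6, (1:6)^2)
  expect_equal(s$rho, 1)
  expect_equal(s$tau, 1)
  expect_equal(s$gamma, 1)
  expect_lt(s$p_gamma, 0.005)

  s2 <- correlation_suite(c(1, 2, 3), c(3, 2, 1))
  expect_equal(s2$r, -1)
  expect_equal(s2$gamma, -1)

  expect_error(correlation_suite(rep(1, 5), 1:5), "constant")
  expect_error(correlation_suite(1:2, 1:2), "n >= 3")
  # ties allowed as long as not constant
  expect_no_error(correlation_suite(rep(c(1, 2), 3), rep(c(1, 2), 3)))
})

test_that("tau-b and gamma match base R / definitional computations", {
  set.seed(11)
  for (i in 1:40) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    s <- correlation_suite(x, y)
    expect_equal(s$tau, cor(x, y, method = "kendall"), tolerance = 1e-12)
    expect_equal(s$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    # gamma from definitional pair counting
    conc <- disc <- 0
    for (a in 1:11) for (b in (a + 1):12) {
      sgn <- sign(x[a] - x[b]) * sign(y[a] - y[b])
      if (sgn > 0) conc <- conc + 1 else if (sgn < 0) disc <- disc + 1
    }
    expect_equal(s$gamma, (conc - disc) / (conc + disc))
    expect_lte(abs(s$tau), abs(s$gamma) + 1e-12)
  }
})

test_that("mann_whitney_u: exact enumeration, oracle agreement, ties", {
  a <- c(0.22, 0.14, 1.04, 0.11, 0.22, 0.14, 0.12, 0.12)
  t <- c(1.05, 1.35, 2.05, 1.95, 2.35, 2.61, 2.08, 2.86)
  res <- mann_whitney_u(a, t)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 12870, tolerance = 1e-12)
  expect_match(res$method, "exact")

  set.seed(5)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:8, 1)), 3)
    y <- round(rnorm(sample(3:8, 1)) + 0.5, 3)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_oracle_distinct(x, y),
                 tolerance = 1e-12)
  }

  ident <- mann_whitney_u(1:4, 1:4)
  expect_equal(ident$statistic, 16 / 2)
  expect_equal(ident$p_value, 1)

  big <- mann_whitney_u(rnorm(30), rnorm(30) + 2)
  expect_match(big$method, "approximation")
  expect_lt(big$p_value, 0.01)
})

test_that("all complete 8-vs-8 separations give exact p = 2/C(16,8)", {
  set.seed(9)
  for (i in 1:5) {
    x <- sort(runif(8))
    y <- sort(runif(8)) + 1.5
    expect_equal(mann_whitney_u(x, y)$p_value, 2 / choose(16, 8),
                 tolerance = 1e-12)
  }
})

test_that("z_test_two_sample and fisher_z_correlation behave as specified", {
  expect_equal(z_test_two_sample(1, 0.5, 1, 0.5)$p_value, 1)
  expect_equal(z_test_two_sample(1.96, 0.6, 0, 0.8)$p_value, 0.05,
               tolerance = 0.001)
  expect_error(z_test_two_sample(1, 0, 2, 1), "positive")

  # group comparison of the strongest verified gene: clearly significant
  t5 <- load_fixture("table5")
  g <- t5[t5$gene == "Ascl3", ]
  sa <- aggregate_group(g[g$group == "aggressive", ])
  st <- aggregate_group(g[g$group == "tame", ])
  z <- z_test_two_sample(st$m0, st$sem, sa$m0, sa$sem)
  expect_gt(z$statistic, 7)
  expect_lt(z$p_value, 0.05)

  fz <- fisher_z_correlation(0.89, 6)
  expect_lt(fz$p_value, 0.05)
  expect_error(fisher_z_correlation(1, 10), "< 1")
})
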