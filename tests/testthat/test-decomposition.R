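pairs <- fixture_pairs()

test_that("pca2 matches the closed form and handles degenerate geometry", {
  x <- c(1, -2, 3, 0.5, -1.2)
  res <- pca2(cbind(x, x))
  expect_equal(res$var_fraction_pc1, 1)
  expect_equal(res$var_fraction_pc2, 0, tolerance = 1e-12)

  # sample correlation exactly zero -> equal split
  x0 <- c(-1, 1, -1, 1); y0 <- c(-1, -1, 1, 1)
  expect_equal(pca2(cbind(x0, y0))$var_fraction_pc1, 0.5)

  expect_error(pca2(cbind(1:2, 2:1)), "at least 3")
  expect_error(pca2(cbind(rep(1, 4), 1:4)), "constant")
})

test_that("correlation-mode PC1 fraction == (1+|r|)/2 on 1000 random datasets", {
  set.seed(314)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    x <- rnorm(n)
    y <- rnorm(n) + runif(1, -2, 2) * x
    res <- pca2(cbind(x, y))
    expect_equal(res$var_fraction_pc1, pc1_fraction_closed_form(cor(x, y)),
                 tolerance = 1e-12)
    expect_equal(res$var_fraction_pc1 + res$var_fraction_pc2, 1,
                 tolerance = 1e-12)
    expect_gte(res$var_fraction_pc1, res$var_fraction_pc2)
  }
})

test_that("pca2 invariances: coordinate swap and affine rescaling", {
  xy <- cbind(pairs$focal_log2fc, pairs$comp_log2fc)
  f1 <- pca2(xy)$var_fraction_pc1
  expect_equal(pca2(xy[, 2:1])$var_fraction_pc1, f1, tolerance = 1e-12)
  scaled <- cbind(3.7 * xy[, 1] - 2, 0.2 * xy[, 2] + 5)
  expect_equal(pca2(scaled)$var_fraction_pc1, f1, tolerance = 1e-12)
  # loadings orthonormal, sign convention on the focal coordinate
  L <- pca2(xy)$loadings
  expect_equal(crossprod(L), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(L[1, ] >= 0))
})

test_that("pc1_fraction_closed_form endpoints and domain", {
  expect_equal(pc1_fraction_closed_form(0), 0.5)
  expect_equal(pc1_fraction_closed_form(1), 1)
  expect_equal(pc1_fraction_closed_form(-0.4), 0.7)
  expect_error(pc1_fraction_closed_form(1.2), "<= 1")
})

test_that("concordance_analysis reproduces the published 2x2 and tests", {
  conc <- concordance_analysis(pairs)
  expect_equal(unclass(conc$table), matrix(c(7L, 2L, 0L, 5L), 2),
               ignore_attr = TRUE)
  expect_equal(conc$chi2$statistic, 7.78, tolerance = 0.005)
  expect_lte(conc$fisher$p_value, 0.05)
  expect_equal(round(conc$binomial_single$p_value, 2), 0.23)
  expect_equal(conc$binomial_multi$p_value, 1 / 128)
})

test_that("concordance counts depend only on signs and not on row order", {
  set.seed(2)
  perm <- pairs[sample(nrow(pairs)), ]
  expect_equal(unclass(concordance_analysis(perm)$table),
               unclass(concordance_analysis(pairs)$table))
  inflated <- pairs
  inflated$focal_log2fc <- inflated$focal_log2fc * 13
  inflated$comp_log2fc <- inflated$comp_log2fc * 0.01
  expect_equal(unclass(concordance_analysis(inflated)$table),
               unclass(concordance_analysis(pairs)$table))
})

test_that("concordance_analysis degenerate inputs", {
  all_same <- pairs
  all_same$comp_log2fc <- abs(all_same$comp_log2fc) *
    sign(all_same$focal_log2fc)
  # the fully concordant table has a zero column margin: chi-square is
  # omitted with a warning, Fisher degenerates to 1
  expect_warning(conc <- concordance_analysis(all_same), "chi-square omitted")
  expect_equal(conc$fisher$p_value, 1)

  zeroed <- pairs
  zeroed$comp_log2fc[1] <- 0
  expect_warning(concordance_analysis(zeroed), "zero log2fc")

  only_par <- pairs[pairs$multiplicity_class == "PARALOG_SUPPORT", ]
  expect_error(concordance_analysis(only_par), "no orthologous")
})

test_that("stratified correlations have the published signs", {
  s <- stratified_correlations(pairs)
  expect_gt(s$multi$r, 0)
  expect_lt(s$single$r, 0)
  expect_equal(s$n_multi + s$n_single, nrow(pairs))

  ss <- stratified_correlations(pairs, "strict")
  expect_equal(ss$n_multi, 7L)
  expect_equal(ss$n_single, 7L)
  expect_gt(ss$multi$r, 0)
  expect_lt(ss$single$r, 0)

  dup <- pairs
  dup$comp_log2fc <- dup$focal_log2fc
  expect_equal(stratified_correlations(dup)$multi$r, 1)

  expect_error(stratified_correlations(pairs[1:2, ]), "fewer than 3")
})
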