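#' Simulate paired log2 fold changes with a common-domestication fraction
#'
#' Generative twin of the two-component interpretation of paired fold
#' changes. Per gene: a sign `s` and two magnitudes are drawn (magnitudes
#' log-uniform over `magnitude_range`, which spans the range of the packaged
#' tables, about 0.25-7.3 absolute log2); with probability `common_fraction`
#' the pair is "common" and the comparison study keeps sign `s`, otherwise
#' the comparison sign is redrawn uniformly (so it flips with probability
#' 1/2). Independent Gaussian noise with standard deviation `noise_sd` is
#' added to each coordinate. The expected sign-concordant share is therefore
#' `f + (1 - f) / 2` (before noise).
#'
#' A single seed initializes the stream and each gene's variates occupy
#' fixed offsets in gene-major order, so any prefix subset of genes is
#' reproducible.
#'
#' @param n_genes Number of gene pairs.
#' @param common_fraction Fraction `f` in `[0, 1]` of sign-conserving genes.
#' @param magnitude_range Positive bounds of the log-uniform magnitude
#'   distribution.
#' @param noise_sd Per-study additive noise SD on the log2 scale.
#' @param seed Integer seed.
#' @return A data frame with columns `gene`, `focal_log2fc`, `comp_log2fc`,
#'   `truth` (`"common"` or `"variable"`).
#' @examples
#' sim <- simulate_paired_log2(54, common_fraction = 0.7, seed = 1)
#' mean(sign(sim$focal_log2fc) == sign(sim$comp_log2fc))
#' @export
simulate_paired_log2 <- function(n_genes = 54, common_fraction = 0.7,
                                 magnitude_range = c(0.25, 7.5),
                                 noise_sd = 0.5, seed = 1) {
  if (n_genes < 1 || common_fraction < 0 || common_fraction > 1 ||
      noise_sd < 0 || any(magnitude_range <= 0) ||
      magnitude_range[1] > magnitude_range[2])
    stop("invalid simulation parameters", call. = FALSE)
  set.seed(as.integer(seed))
  # gene-major variate layout: 7 uniform draws per gene at fixed offsets,
  # so a run with fewer genes is a prefix of a run with more
  u <- matrix(runif(7 * n_genes), ncol = 7, byrow = TRUE)
  lmr <- log(magnitude_range)
  s <- ifelse(u[, 1] < 0.5, -1, 1)
  m1 <- exp(lmr[1] + u[, 2] * (lmr[2] - lmr[1]))
  m2 <- exp(lmr[1] + u[, 3] * (lmr[2] - lmr[1]))
  common <- u[, 4] < common_fraction
  s2 <- ifelse(common, s, ifelse(u[, 5] < 0.5, -1, 1))
  # per-gene Gaussian noise via inverse transform of the same stream
  noise <- stats::qnorm(u[, 6:7, drop = FALSE]) * noise_sd
  data.frame(gene = paste0("g", seq_len(n_genes)),
             focal_log2fc = s * m1 + noise[, 1],
             comp_log2fc = s2 * m2 + noise[, 2],
             truth = ifelse(common, "common", "variable"),
             stringsAsFactors = FALSE)
}

#' Simulate a qPCR per-animal relative-expression table
#'
#' Per-animal values are drawn log-normally around the group means with
#' coefficient of variation `cv` (moment-matched: the log-normal mean equals
#' the group mean). Values below `detection_limit` are flagged not-detected
#' and their `rel_expr` set to `NA`, mirroring the behaviour of the packaged
#' qPCR table. Defaults mirror that table's design: 8 animals per group and
#' group means equal to the strongest verified gene's published means.
#'
#' @param n_per_group Animals per group.
#' @param group_means Named or ordered pair of positive means
#'   `(aggressive, tame)`.
#' @param cv Coefficient of variation of the per-animal values.
#' @param detection_limit Positive threshold below which a value is ND.
#' @param gene Gene label for the output rows.
#' @param seed Integer seed.
#' @return A data frame with columns `gene`, `group`, `animal_id`,
#'   `behavior_score`, `rel_expr`, `nd_flag`.
#' @export
simulate_qpcr <- function(n_per_group = 8, group_means = c(aggressive = 0.26,
                                                           tame = 2.04),
                          cv = 0.5, detection_limit = 0.01, gene = "simGene",
                          seed = 1) {
  if (n_per_group < 1 || any(group_means <= 0) || cv < 0 ||
      detection_limit <= 0)
    stop("invalid simulation parameters", call. = FALSE)
  set.seed(as.integer(seed))
  labels <- names(group_means)
  if (is.null(labels)) labels <- c("aggressive", "tame")
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(mn) {
    if (cv == 0) rep(mn, n_per_group)
    else exp(rnorm(n_per_group, mean = log(mn) - sdlog^2 / 2, sd = sdlog))
  }
  rows <- lapply(seq_along(group_means), function(g) {
    v <- draw(group_means[g])
    nd <- v < detection_limit
    data.frame(gene = gene, group = labels[g],
               animal_id = seq_len(n_per_group),
               behavior_score = if (labels[g] == "tame") 3L else -3L,
               rel_expr = ifelse(nd, NA_real_, v),
               nd_flag = nd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
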