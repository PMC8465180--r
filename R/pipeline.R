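#' Pipeline configuration
#'
#' Validates and bundles the options of [run_pipeline()]. All paths are
#' optional: `NULL` path slots fall back to the packaged fixture tables (or
#' disable the stage where indicated).
#'
#' @param focal_path,comparison_path TSV paths of focal and comparison DEG
#'   tables (`NULL`: packaged tables).
#' @param maps_path JSON path of the curated homology maps (`NULL`:
#'   packaged maps).
#' @param qpcr_path TSV path of per-animal qPCR rows (`NULL`: packaged
#'   table); set `qpcr = FALSE` to skip the stage.
#' @param human_annotations_path,human_animal_path TSV paths for the human
#'   mapping stage (`NULL`: packaged tables); set `human = FALSE` to skip.
#' @param pca_mode `"correlation"` or `"covariance"`.
#' @param fisher_sided `"one"` or `"two"`.
#' @param stratum_membership `"inclusive"` or `"strict"` (see
#'   [stratified_correlations()]).
#' @param nd_detection_limit Imputation value for not-detected qPCR animals.
#' @param alpha Significance level in `(0, 1)`.
#' @param use_fallback Enable the shared-prefix pairing heuristic.
#' @param qpcr,human Logical stage switches.
#' @param seed Integer seed echoed into the report (the fixture pipeline is
#'   deterministic; the seed matters when stages consume simulated input).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(focal_path = NULL, comparison_path = NULL,
                            maps_path = NULL, qpcr_path = NULL,
                            human_annotations_path = NULL,
                            human_animal_path = NULL,
                            pca_mode = "correlation",
                            fisher_sided = "one",
                            stratum_membership = "inclusive",
                            nd_detection_limit = 0.01,
                            alpha = 0.05,
                            use_fallback = TRUE,
                            qpcr = TRUE, human = TRUE,
                            seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  pca_mode <- match.arg(pca_mode, c("correlation", "covariance"))
  fisher_sided <- match.arg(fisher_sided, c("one", "two"))
  stratum_membership <- match.arg(stratum_membership,
                                  c("inclusive", "strict"))
  for (p in c(focal_path, comparison_path, maps_path, qpcr_path,
              human_annotations_path, human_animal_path))
    if (!is.null(p) && !file.exists(p))
      stop("path not resolvable: ", p, call. = FALSE)
  structure(list(focal_path = focal_path, comparison_path = comparison_path,
                 maps_path = maps_path, qpcr_path = qpcr_path,
                 human_annotations_path = human_annotations_path,
                 human_animal_path = human_animal_path,
                 pca_mode = pca_mode, fisher_sided = fisher_sided,
                 stratum_membership = stratum_membership,
                 nd_detection_limit = nd_detection_limit,
                 alpha = alpha, use_fallback = use_fallback,
                 qpcr = isTRUE(qpcr), human = isTRUE(human),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.tr_json <- function(tr) {
  if (is.null(tr)) return(NULL)
  list(statistic = tr$statistic, p_value = tr$p_value, sided = tr$sided,
       method = tr$method)
}

.suite_json <- function(s) {
  s[c("r", "p_r", "rho", "p_rho", "tau", "p_tau", "gamma", "p_gamma", "n")]
}

#' Run the full concordance pipeline
#'
#' Executes pair compilation, multiplicity classification, the
#' sign-concordance contingency analysis, the two-variable PCA, the
#' stratified correlations, the qPCR verification, and the human
#' reproductive-potential mapping, and returns one structured report. Every
#' statistic in the report records its method and sidedness; input file
#' checksums and all convention switches are echoed so published-value
#' comparisons are auditable. Re-running with the same configuration and
#' inputs reproduces the report exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, `report.json` and
#'   `pairs.tsv` are written there.
#' @return The report, a list of class `pipeline_report`.
#' @examples
#' rep <- run_pipeline(pipeline_config())
#' round(100 * rep$decomposition$var_fraction_pc1)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  inputs <- list()
  focal <- stage("load_focal", {
    if (is.null(config$focal_path)) load_fixture("table4")
    else read_deg_table(config$focal_path)
  })
  comparison <- stage("load_comparison", {
    if (is.null(config$comparison_path)) table6_comparison_degs()
    else read_deg_table(config$comparison_path)
  })
  maps <- stage("load_maps", {
    if (is.null(config$maps_path)) load_fixture("maps")
    else read_homology_maps(config$maps_path)
  })
  for (nm in c("focal_path", "comparison_path", "maps_path", "qpcr_path",
               "human_annotations_path", "human_animal_path")) {
    p <- config[[nm]]
    if (!is.null(p)) inputs[[nm]] <- list(path = p,
                                          md5 = unname(tools::md5sum(p)))
  }

  pairs <- stage("pair", classify_pairs(
    pair_homologs(focal, comparison, maps,
                  use_fallback = config$use_fallback)))
  conc <- stage("concordance", concordance_analysis(pairs))
  pca <- stage("decompose", pca2(pairs, mode = config$pca_mode))
  strat <- stage("stratified_correlations",
                 stratified_correlations(pairs, config$stratum_membership))

  report <- list(
    schema_version = "1.0",
    config = unclass(config),
    inputs = inputs,
    homology = list(
      n_pairs = nrow(pairs),
      class_counts = as.list(table(pairs$multiplicity_class))),
    concordance = list(
      table = unclass(conc$table),
      fisher = .tr_json(conc$fisher),
      chi2 = .tr_json(conc$chi2),
      binomial_multi = .tr_json(conc$binomial_multi),
      binomial_single = .tr_json(conc$binomial_single)),
    decomposition = list(
      mode = pca$mode,
      var_fraction_pc1 = pca$var_fraction_pc1,
      var_fraction_pc2 = pca$var_fraction_pc2,
      loadings = unclass(pca$loadings),
      closed_form_pc1 = pc1_fraction_closed_form(
        cor(pairs$focal_log2fc, pairs$comp_log2fc))),
    stratified = list(
      membership = strat$membership,
      multi = .suite_json(strat$multi),
      single = .suite_json(strat$single)))

  if (config$qpcr) {
    report$qpcr <- stage("qpcr_verify", {
      t5 <- if (is.null(config$qpcr_path)) load_fixture("table5") else {
        x <- read.delim(config$qpcr_path, stringsAsFactors = FALSE,
                        colClasses = c(rel_expr = "character"))
        x$nd_flag <- x$rel_expr == "ND"
        x$rel_expr <- suppressWarnings(as.numeric(x$rel_expr))
        x
      }
      fl <- focal
      fl$canon <- normalize_symbol(fl$symbol, maps)
      lapply(split(t5, t5$gene), function(gs) {
        canon <- normalize_symbol(gs$gene[1], maps)
        rl <- fl$log2fc[match(canon, fl$canon)]
        v <- verify_deg(gs, rnaseq_log2 = rl, alpha = config$alpha,
                        detection_limit = config$nd_detection_limit)
        list(gene = v$gene, qpcr_log2 = v$qpcr_log2,
             rnaseq_log2 = v$rnaseq_log2,
             sign_agreement = v$sign_agreement,
             significant = v$significant,
             mann_whitney = .tr_json(v$mann_whitney),
             z_test = .tr_json(v$z_test))
      })
    })
  }

  if (config$human) {
    report$human <- stage("human_map", {
      t8 <- load_fixture("table8")
      ann <- if (is.null(config$human_annotations_path)) t8$human else
        read.delim(config$human_annotations_path, stringsAsFactors = FALSE)
      ani <- if (is.null(config$human_animal_path)) t8$animal else
        read.delim(config$human_animal_path, stringsAsFactors = FALSE)
      res <- build_reproductive_table(human_divergence_calls(ani, ann))
      list(table = unclass(res$table),
           chi2 = .tr_json(res$chi2),
           fisher = .tr_json(res$fisher),
           binomial_domestic = .tr_json(res$binomial_domestic),
           binomial_wild = .tr_json(res$binomial_wild),
           n_calls = res$n_calls)
    })
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  report
}
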