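#' Assign divergence sides from a log2 fold change
#'
#' The log2 fold change has the domestic/tame group in the numerator, so a
#' negative value means the gene is under-expressed in the domestic form and
#' (relative to the most recent common ancestor) over-expressed in the wild
#' form; a positive value means the opposite. Zero has no sign and is an
#' error.
#'
#' @param log2fc Non-zero log2 fold change (domestic over wild).
#' @return A list with `domestic_state` and `wild_state`, each `"deficit"`
#'   or `"excess"`.
#' @examples
#' assign_divergence_sides(-3.97)  # domestic deficit, wild excess
#' @export
assign_divergence_sides <- function(log2fc) {
  if (length(log2fc) != 1 || !is.finite(log2fc))
    stop("log2fc must be a single finite value", call. = FALSE)
  if (log2fc == 0) stop("zero log2fc: divergence side undefined", call. = FALSE)
  if (log2fc < 0) list(domestic_state = "deficit", wild_state = "excess")
  else list(domestic_state = "excess", wild_state = "deficit")
}

#' Map divergence sides through a human effect annotation
#'
#' Given the deficit/excess state on each divergence side and the human
#' ortholog's effect annotation (what a deficit and an excess of the gene do
#' to reproductive potential), derives the mapped effect for the domestic and
#' the wild side.
#'
#' @param sides Output of [assign_divergence_sides()] (or a single log2fc,
#'   converted internally).
#' @param annotation A one-row data frame or list with `human_gene`,
#'   `effect_of_deficit` and `effect_of_excess` (each `"decreased"` or
#'   `"increased"`).
#' @return A list of class `divergence_call`: `human_gene`,
#'   `domestic_state`, `wild_state`, `domestic_effect`, `wild_effect`.
#' @export
map_to_human_effect <- function(sides, annotation) {
  if (is.numeric(sides)) sides <- assign_divergence_sides(sides)
  eff <- c(deficit = annotation$effect_of_deficit,
           excess = annotation$effect_of_excess)
  if (any(is.na(eff)) || !all(eff %in% c("decreased", "increased")))
    stop("annotation effects must be 'decreased' or 'increased'", call. = FALSE)
  structure(list(human_gene = annotation$human_gene,
                 domestic_state = sides$domestic_state,
                 wild_state = sides$wild_state,
                 domestic_effect = unname(eff[sides$domestic_state]),
                 wild_effect = unname(eff[sides$wild_state])),
            class = "divergence_call")
}

#' Build divergence calls for a table of animal DEG rows
#'
#' Joins each animal DEG row to its human ortholog's effect annotation and
#' maps the log2 sign through it.
#'
#' @param animal Data frame with columns `human_gene`, `animal_deg`,
#'   `log2fc` (as from `load_fixture("table8")$animal`).
#' @param annotations Data frame with columns `human_gene`,
#'   `effect_of_deficit`, `effect_of_excess`.
#' @return A list of `divergence_call` objects.
#' @export
human_divergence_calls <- function(animal, annotations) {
  stopifnot(all(c("human_gene", "log2fc") %in% names(animal)),
            all(c("human_gene", "effect_of_deficit", "effect_of_excess")
                %in% names(annotations)))
  lapply(seq_len(nrow(animal)), function(i) {
    g <- animal$human_gene[i]
    ann <- annotations[annotations$human_gene == g, , drop = FALSE]
    if (nrow(ann) != 1)
      stop("missing (or ambiguous) annotation for human gene ", g,
           call. = FALSE)
    call <- map_to_human_effect(animal$log2fc[i], as.list(ann))
    call$animal_deg <- if ("animal_deg" %in% names(animal))
      animal$animal_deg[i] else NA_character_
    call
  })
}

#' Contingency analysis of mapped reproductive-potential effects
#'
#' Tallies the divergence calls into the 2x2 table of divergence side
#' (rows: domestic, wild) by mapped effect on human reproductive potential
#' (columns: decreased, increased); each call contributes one count to each
#' row. Runs the uncorrected Pearson chi-square, one-sided Fisher exact test
#' and majority-direction binomial sign test per row.
#'
#' @param calls List of `divergence_call` objects.
#' @return A list of class `reproductive_table`: `table`, `chi2`, `fisher`,
#'   `binomial_domestic`, `binomial_wild`, `n_calls`.
#' @examples
#' t8 <- load_fixture("table8")
#' res <- build_reproductive_table(human_divergence_calls(t8$animal, t8$human))
#' res$table            # [[13, 1], [7, 7]]
#' res$chi2$statistic   # 6.30
#' @export
build_reproductive_table <- function(calls) {
  if (!length(calls)) stop("no divergence calls", call. = FALSE)
  dom <- vapply(calls, function(cl) cl$domestic_effect, character(1))
  wld <- vapply(calls, function(cl) cl$wild_effect, character(1))
  tab <- xtab2x2(sum(dom == "decreased"), sum(dom == "increased"),
                 sum(wld == "decreased"), sum(wld == "increased"),
                 row_labels = c("domestic", "wild"),
                 col_labels = c("decreased", "increased"))
  chi2 <- tryCatch(chi2_2x2(tab), error = function(e) NULL)
  row_binom <- function(counts) binomial_sign_test(max(counts), sum(counts))
  structure(list(table = tab, chi2 = chi2,
                 fisher = fisher_exact_2x2(tab, sided = "one"),
                 binomial_domestic = row_binom(tab[1, ]),
                 binomial_wild = row_binom(tab[2, ]),
                 n_calls = length(calls)),
            class = "reproductive_table")
}
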