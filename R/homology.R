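#' Curated homology maps
#'
#' Container for the three curated symbol maps used when pairing homologous
#' DEGs: `alias_map` (raw symbol -> canonical symbol; bridges spelling
#' variants such as Mre11/Mre11a), `ortholog_map` (focal canonical symbol ->
#' comparison symbols accepted as cross-species orthologs beyond exact symbol
#' identity), and `family_map` (canonical symbol -> gene-family root used for
#' paralog support). All keys and values are stored in canonical (lowercase)
#' form.
#'
#' @param alias_map Named character vector or list.
#' @param ortholog_map Named list of character vectors.
#' @param family_map Named character vector or list.
#' @return An object of class `homology_maps`.
#' @export
homology_maps <- function(alias_map = character(),
                          ortholog_map = list(),
                          family_map = character()) {
  alias_map <- unlist(alias_map)
  family_map <- unlist(family_map)
  if (is.null(alias_map)) alias_map <- character()
  if (is.null(family_map)) family_map <- character()
  ortholog_map <- lapply(ortholog_map, as.character)
  # alias map must be idempotent: targets may not themselves be aliased
  if (length(alias_map) && any(alias_map %in% names(alias_map)[alias_map != names(alias_map)]))
    stop("alias_map is not idempotent", call. = FALSE)
  if (length(family_map) && any(!nzchar(family_map)))
    stop("family roots must be non-empty", call. = FALSE)
  structure(list(alias_map = alias_map,
                 ortholog_map = ortholog_map,
                 family_map = family_map),
            class = "homology_maps")
}

#' Read homology maps from JSON
#'
#' @param path Path to a JSON file with members `alias_map`, `ortholog_map`
#'   and `family_map`.
#' @return A [homology_maps()] object.
#' @export
read_homology_maps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  homology_maps(alias_map = j$alias_map,
                ortholog_map = as.list(j$ortholog_map),
                family_map = j$family_map)
}

#' Write homology maps to JSON
#'
#' @param maps A [homology_maps()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_maps <- function(maps, path) {
  stopifnot(inherits(maps, "homology_maps"))
  jsonlite::write_json(list(alias_map = as.list(maps$alias_map),
                            ortholog_map = maps$ortholog_map,
                            family_map = as.list(maps$family_map)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Normalize a gene symbol
#'
#' Strips markup (asterisks, backticks, whitespace), converts the typographic
#' minus to ASCII, lowercases, and applies the curated alias map. Hyphens that
#' are part of a symbol (e.g. `Hbb-b1`) are preserved. Vectorized over `raw`.
#'
#' @param raw Character vector of raw symbols.
#' @param alias_map Named character vector (raw canonical -> aliased
#'   canonical), or a [homology_maps()] object.
#' @return Character vector of canonical symbols.
#' @examples
#' normalize_symbol("*Ascl3*")                      # "ascl3"
#' normalize_symbol("Mre11", c(mre11 = "mre11a"))   # "mre11a"
#' @export
normalize_symbol <- function(raw, alias_map = character()) {
  if (inherits(alias_map, "homology_maps")) alias_map <- alias_map$alias_map
  if (any(is.na(raw) | !nzchar(trimws(raw))))
    stop("empty gene symbol", call. = FALSE)
  s <- tolower(gsub("[*`[:space:]]", "", .ascii_minus(raw)))
  hit <- s %in% names(alias_map)
  s[hit] <- unname(unlist(alias_map)[s[hit]])
  s
}

#' Family root of a canonical symbol
#'
#' Returns the curated gene-family root when the symbol has a `family_map`
#' entry, otherwise the symbol itself. Shared-prefix grouping of two uncurated
#' symbols is a pairing-time heuristic, see [pair_homologs()].
#'
#' @param symbol Character vector of canonical (normalized) symbols.
#' @param family_map Named character vector, or a [homology_maps()] object.
#' @return Character vector of family roots.
#' @examples
#' maps <- load_fixture("maps")
#' family_root("hbb-b1", maps)  # "hb"
#' family_root("banp", maps)    # "banp" (no curated family)
#' @export
family_root <- function(symbol, family_map = character()) {
  if (inherits(family_map, "homology_maps")) family_map <- family_map$family_map
  out <- symbol
  hit <- symbol %in% names(family_map)
  out[hit] <- unname(unlist(family_map)[symbol[hit]])
  out
}

# Longest shared leading alphabetic prefix of two symbols ("" if none).
.shared_alpha_prefix <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- min(length(ca), length(cb))
  k <- 0L
  while (k < n && ca[k + 1L] == cb[k + 1L] && grepl("[a-z]", ca[k + 1L]))
    k <- k + 1L
  substr(a, 1L, k)
}

#' Compile homologous DEG pairs between a focal and a comparison study set
#'
#' Performs the Cartesian match of focal DEG records against comparison DEG
#' records, restricted to (a) curated orthology -- identical canonical symbol
#' or an explicit `ortholog_map` entry -- giving relation `ORTHOLOG`, and
#' (b) a shared gene-family root giving relation `PARALOG_SUPPORT`. When both
#' symbols lack a curated family entry and `use_fallback` is `TRUE`, a shared
#' leading alphabetic prefix of at least `min_prefix` characters counts as a
#' shared root; a curated entry on either side always wins over the
#' heuristic. Each (focal record, comparison record) combination is emitted
#' at most once, with `ORTHOLOG` taking precedence.
#'
#' @param focal_degs,comparison_degs `deg_table` data frames.
#' @param maps A [homology_maps()] object.
#' @param use_fallback Enable the shared-prefix heuristic for symbols without
#'   curated family entries (`FALSE` gives a strict-curation run).
#' @param min_prefix Minimum shared alphabetic prefix length for the fallback.
#' @return A `homolog_pairs` data frame sorted by (focal symbol, comparison
#'   symbol, source, tissue), with columns `pair_id`, `focal_symbol`,
#'   `focal_log2fc`, `comp_symbol`, `comp_log2fc`, `comp_species`,
#'   `comp_tissue`, `source_id`, `relation` and `sign_concordant`.
#' @examples
#' pairs <- pair_homologs(load_fixture("table4"), table6_comparison_degs(),
#'                        load_fixture("maps"))
#' nrow(pairs)  # 54
#' @export
pair_homologs <- function(focal_degs, comparison_degs, maps,
                          use_fallback = TRUE, min_prefix = 2L) {
  validate_deg_table(focal_degs)
  validate_deg_table(comparison_degs)
  stopifnot(inherits(maps, "homology_maps"))
  if (!nrow(focal_degs) || !nrow(comparison_degs))
    stop("both DEG lists must be non-empty", call. = FALSE)

  fsym <- normalize_symbol(focal_degs$symbol, maps)
  csym <- normalize_symbol(comparison_degs$symbol, maps)
  froot <- family_root(fsym, maps)
  croot <- family_root(csym, maps)
  fcur <- fsym %in% names(maps$family_map)
  ccur <- csym %in% names(maps$family_map)

  rows <- vector("list", nrow(focal_degs))
  for (i in seq_len(nrow(focal_degs))) {
    accepted <- maps$ortholog_map[[fsym[i]]]
    is_orth <- csym == fsym[i] | (if (is.null(accepted)) FALSE else csym %in% accepted)
    is_par <- froot[i] == croot & !is_orth
    if (use_fallback && !fcur[i]) {
      unc <- which(!ccur & !is_orth & !is_par)
      for (j in unc) {
        if (nchar(.shared_alpha_prefix(fsym[i], csym[j])) >= min_prefix)
          is_par[j] <- TRUE
      }
    }
    hit <- which(is_orth | is_par)
    if (!length(hit)) next
    rows[[i]] <- data.frame(
      focal_symbol = fsym[i],
      focal_log2fc = focal_degs$log2fc[i],
      comp_symbol = csym[hit],
      comp_log2fc = comparison_degs$log2fc[hit],
      comp_species = if ("species" %in% names(comparison_degs))
        comparison_degs$species[hit] else NA_character_,
      comp_tissue = if ("tissue" %in% names(comparison_degs))
        comparison_degs$tissue[hit] else NA_character_,
      source_id = if ("source_id" %in% names(comparison_degs))
        comparison_degs$source_id[hit] else NA_character_,
      relation = ifelse(is_orth[hit], "ORTHOLOG", "PARALOG_SUPPORT"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(focal_symbol = character(), focal_log2fc = numeric(),
                      comp_symbol = character(), comp_log2fc = numeric(),
                      comp_species = character(), comp_tissue = character(),
                      source_id = character(), relation = character(),
                      stringsAsFactors = FALSE)
  ord <- order(out$focal_symbol, out$comp_symbol, out$source_id, out$comp_tissue)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$pair_id <- seq_len(nrow(out))
  out$sign_concordant <- out$focal_log2fc * out$comp_log2fc > 0
  class(out) <- unique(c("homolog_pairs", class(out)))
  out
}

#' Comparison-study DEG records of the packaged homolog-pair table
#'
#' Extracts the comparison half of the packaged 54-pair table as a standalone
#' `deg_table`, suitable as the `comparison_degs` argument of
#' [pair_homologs()].
#'
#' @return A `deg_table` with 54 records.
#' @export
table6_comparison_degs <- function() {
  t6 <- load_fixture("table6")
  out <- data.frame(symbol = t6$comp_symbol,
                    log2fc = t6$comp_log2fc,
                    species = t6$domestic,
                    tissue = t6$tissue,
                    p_adj = t6$comp_p_adj,
                    source_id = t6$source_id,
                    stringsAsFactors = FALSE)
  out <- validate_deg_table(out)
  out
}

#' Classify homologous pairs by homology multiplicity
#'
#' For each focal gene, `k` is the total number of pairs (any relation) the
#' gene participates in. Orthologous pairs of a focal gene with `k >= 2` are
#' classed `ORTHOLOG_MULTI` (supported by other homologs); orthologous pairs
#' of a focal gene with `k = 1` are `ORTHOLOG_SINGLE` (stand-alone);
#' paralog-support pairs keep class `PARALOG_SUPPORT`. The classification is
#' idempotent and independent of row order.
#'
#' @param pairs A `homolog_pairs` data frame from [pair_homologs()].
#' @return `pairs` with a `multiplicity_class` column added/refreshed.
#' @export
classify_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("focal_symbol", "relation") %in% names(pairs)))
  k <- table(pairs$focal_symbol)
  kk <- as.integer(k[pairs$focal_symbol])
  pairs$multiplicity_class <- ifelse(
    pairs$relation == "ORTHOLOG",
    ifelse(kk >= 2L, "ORTHOLOG_MULTI", "ORTHOLOG_SINGLE"),
    "PARALOG_SUPPORT")
  pairs
}
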