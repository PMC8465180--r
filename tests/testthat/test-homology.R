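maps <- load_fixture("maps")

test_that("normalize_symbol strips markup, lowercases, applies aliases", {
  expect_equal(normalize_symbol("*Ascl3*"), "ascl3")
  expect_equal(normalize_symbol("Hbb-b1"), "hbb-b1")
  expect_equal(normalize_symbol("Mre11", c(mre11 = "mre11a")), "mre11a")
  expect_equal(normalize_symbol("Mre11", maps), "mre11a")
  # idempotent
  expect_equal(normalize_symbol(normalize_symbol("Mre11", maps), maps),
               normalize_symbol("Mre11", maps))
  expect_error(normalize_symbol(""), "empty")
  expect_error(homology_maps(alias_map = c(a = "b", b = "c")),
               "idempotent")
})

test_that("family_root returns curated roots, symbol itself otherwise", {
  expect_equal(family_root("hbb-b1", maps), "hb")
  expect_equal(family_root("pla2g2c", maps), "pla")
  expect_equal(family_root("banp", maps), "banp")
  expect_equal(family_root(c("hbbl", "krt17", "xyz"), maps),
               c("hb", "krt", "xyz"))
})

test_that("pair_homologs reproduces the curated 54-pair table", {
  pairs <- pair_homologs(load_fixture("table4"), table6_comparison_degs(),
                         maps)
  expect_equal(nrow(pairs), 54L)
  expect_equal(sum(pairs$relation == "ORTHOLOG"), 14L)
  # strict-curation run (no prefix fallback) gives the same pairing
  strict <- pair_homologs(load_fixture("table4"), table6_comparison_degs(),
                          maps, use_fallback = FALSE)
  expect_equal(strict[names(strict) != "pair_id"],
               pairs[names(pairs) != "pair_id"])
  # every source row is recovered exactly once
  expect_setequal(fixture_pair_rows(pairs), 1:54)
})

test_that("pair_homologs emits per-study ortholog duplicates and empties", {
  focal <- data.frame(symbol = "Cd22", log2fc = 2.85)
  comparison <- data.frame(symbol = c("Cd22", "Cd22"), log2fc = c(2.34, 0.32),
                           species = c("dogs", "foxes"),
                           tissue = c("blood", "pituitary"),
                           source_id = c("B24", "B23"))
  p <- pair_homologs(focal, comparison, maps)
  expect_equal(nrow(p), 2L)
  expect_true(all(p$relation == "ORTHOLOG"))

  none <- pair_homologs(data.frame(symbol = "Zzz9", log2fc = 1),
                        data.frame(symbol = "Qqq1", log2fc = 1), maps)
  expect_equal(nrow(none), 0L)
})

test_that("prefix fallback pairs uncurated symbols but curation wins", {
  m0 <- homology_maps()
  p <- pair_homologs(data.frame(symbol = "Hbxa", log2fc = 1),
                     data.frame(symbol = "Hbxb", log2fc = -1), m0)
  expect_equal(p$relation, "PARALOG_SUPPORT")
  p0 <- pair_homologs(data.frame(symbol = "Hbxa", log2fc = 1),
                      data.frame(symbol = "Hbxb", log2fc = -1), m0,
                      use_fallback = FALSE)
  expect_equal(nrow(p0), 0L)
  # curated family entry on one side disables the heuristic for that symbol
  mcur <- homology_maps(family_map = c(hbxb = "other"))
  expect_equal(nrow(pair_homologs(data.frame(symbol = "Hbxa", log2fc = 1),
                                  data.frame(symbol = "Hbxb", log2fc = -1),
                                  mcur)), 0L)
})

test_that("classify_pairs reproduces the published multiplicity classes", {
  pairs <- fixture_pairs()
  rows <- fixture_pair_rows(pairs)
  expect_equal(sort(rows[pairs$multiplicity_class == "ORTHOLOG_MULTI"]),
               c(1L, 2L, 3L, 4L, 10L, 29L, 30L))
  expect_equal(sort(rows[pairs$multiplicity_class == "ORTHOLOG_SINGLE"]),
               c(6L, 9L, 28L, 34L, 51L, 52L, 53L))
  expect_equal(sum(pairs$multiplicity_class == "PARALOG_SUPPORT"), 40L)
})

test_that("classification invariants: partition, single-pair, idempotence, order", {
  pairs <- fixture_pairs()
  cls <- table(pairs$multiplicity_class)
  expect_equal(sum(cls), nrow(pairs))

  singles <- pairs$focal_symbol[pairs$multiplicity_class == "ORTHOLOG_SINGLE"]
  expect_true(all(table(pairs$focal_symbol)[singles] == 1L))

  expect_equal(classify_pairs(pairs), pairs)

  set.seed(7)
  shuffled <- classify_pairs(pairs[sample(nrow(pairs)), ])
  shuffled <- shuffled[order(shuffled$pair_id), ]
  rownames(shuffled) <- NULL
  expect_equal(shuffled, pairs)
})

test_that("sign_concordant matches the product-of-signs definition", {
  pairs <- fixture_pairs()
  expect_equal(pairs$sign_concordant,
               pairs$focal_log2fc * pairs$comp_log2fc > 0)
})

test_that("homology maps round-trip through JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_homology_maps(maps, tmp)
  back <- read_homology_maps(tmp)
  expect_equal(back$alias_map, maps$alias_map)
  expect_equal(back$family_map, maps$family_map)
  expect_equal(back$ortholog_map, maps$ortholog_map)
})
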