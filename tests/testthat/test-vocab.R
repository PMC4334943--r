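test_that("vocabulary files load and enforce their invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term_id\tlabel\tsynonyms\tparents",
               "X:1\troot\t\t",
               "X:2\tsoil\tdirt\tX:1",
               "X:3\twater\t\tX:1"), path)
  v <- read_vocabulary(path, "mini")
  expect_s3_class(v, "controlled_vocabulary")
  expect_length(v$terms, 3)
  # duplicate case-folded labels name both offenders
  writeLines(c("term_id\tlabel\tsynonyms\tparents",
               "X:1\tsoil\t\t", "X:2\tSOIL\t\t"), path)
  expect_error(read_vocabulary(path), "X:1.*X:2", class = "mixsheet_schema_error")
  # dangling parents are schema errors
  writeLines(c("term_id\tlabel\tsynonyms\tparents",
               "X:1\tsoil\t\tX:99"), path)
  expect_error(read_vocabulary(path), "X:99", class = "mixsheet_schema_error")
})

test_that("the bundled biome subset resolves marine biome", {
  biome <- fx_vocabs()$biome
  t <- resolve_term(biome, "marine biome")
  expect_false(is.null(t))
  expect_equal(t$label, "marine biome")
})

test_that("resolve_term matches id, label and synonym case-insensitively with trimming", {
  biome <- fx_vocabs()$biome
  t <- resolve_term(biome, "  MARINE BIOME  ")
  expect_equal(t$label, "marine biome")
  expect_equal(resolve_term(biome, t$term_id), t)
  expect_equal(resolve_term(biome, "SEA BIOME")$label, "marine biome")  # synonym
  expect_null(resolve_term(biome, "not_a_real_biome"))
  expect_null(resolve_term(biome, ""))
})

test_that("every term resolves through its own label and id (identity property)", {
  for (v in fx_vocabs()) {
    for (t in v$terms) {
      expect_identical(resolve_term(v, t$label), t)
      expect_identical(resolve_term(v, t$term_id), t)
    }
  }
})

test_that("search_terms agrees with the brute-force ranking oracle", {
  biome <- fx_vocabs()$biome
  # empty query: first `limit` terms in label order
  expect_equal(search_terms(biome, "", 3), brute_force_search(biome, "", 3))
  # an exact label is ranked first
  expect_equal(search_terms(biome, "forest biome", 5)[[1]]$label, "forest biome")
  # assorted queries, including substring and synonym-only hits
  for (q in c("mar", "biome", "FRESH", "ine b", "steppe", "zzz", "  lake ")) {
    expect_equal(search_terms(biome, q, 50), brute_force_search(biome, q, 50),
                 info = paste("query:", q))
  }
  expect_length(search_terms(biome, "biome", 1), 1)
  expect_error(search_terms(biome, "x", 0), class = "mixsheet_argument_error")
})

test_that("the OBO importer produces an equivalent vocabulary", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: X:1", "name: biome", "",
    "[Term]", "id: X:2", "name: marine biome",
    'synonym: "sea biome" EXACT []', "is_a: X:1 ! biome", "",
    "[Term]", "id: X:3", "name: old biome", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), path)
  v <- read_obo_vocabulary(path, "obo_mini")
  expect_length(v$terms, 2)
  expect_equal(resolve_term(v, "sea biome")$term_id, "X:2")
  expect_equal(resolve_term(v, "marine biome")$parents, "X:1")
  expect_null(resolve_term(v, "old biome"))
})

test_that("vocabularies round trip through their TSV form", {
  for (v in fx_vocabs()) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_vocabulary(v, path)
    expect_equal(read_vocabulary(path, v$name)$terms, v$terms)
  }
})
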