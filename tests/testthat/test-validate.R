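test_that("level 1 reports exactly the data-type violations of defined keys", {
  tpl <- tiny_template()
  vocabs <- fx_vocabs()
  b <- add_sample(new_bundle(tpl, "p1"), "s1",
                  list(collection_date = "31/12/2014", latitude = "95.0",
                       biome = "marine biome"), "water")
  rep <- validate_values(b, tpl, vocabs)
  expect_equal(sort(rep$code), c("not_iso_date", "out_of_range"))
  expect_equal(rep$severity, rep(c("error"), 2))
  # keys outside the template are skipped at level 1
  b2 <- set_value(b, "s1", "my_custom_note", "12/12/12")
  expect_equal(nrow(validate_values(b2, tpl, vocabs)), 2)
  # a CV violation is one error
  b3 <- set_value(b, "s1", "biome", "not_a_real_biome")
  rep3 <- validate_values(b3, tpl, vocabs)
  expect_equal(sum(rep3$code == "cv_violation"), 1)
})

test_that("a blank required contact-organization field yields exactly one missing_required", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  b <- make_valid_bundle(tpl, vocabs, seed = 2, n_samples = 1)
  b <- set_value(b, b$project$id, "pi_organization", "")
  rep <- validate_bundle(b, tpl, vocabs)
  expect_false(is_valid(rep))
  expect_equal(nrow(rep), 1)
  expect_equal(rep$code, "missing_required")
  expect_equal(rep$key, "pi_organization")
})

test_that("an empty entity yields one missing_required per required field", {
  tpl <- fx_template()
  b <- new_bundle(tpl, "p1")
  rep <- validate_structure(b, tpl)
  k <- length(required_fields(tpl, "project"))
  expect_equal(sum(rep$code == "missing_required"), k)
  expect_equal(sum(rep$code == "no_samples"), 1)
  expect_equal(nrow(rep), k + 1)
})

test_that("extra keys are warnings and never invalidate", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  b <- make_valid_bundle(tpl, vocabs, seed = 3, n_samples = 1)
  b <- set_value(b, "sample_01", "my_custom_note", "kept, not validated")
  rep <- validate_bundle(b, tpl, vocabs)
  expect_equal(rep$code, "unknown_key")
  expect_equal(rep$severity, "warning")
  expect_true(is_valid(rep))
})

test_that("hierarchy violations surface as structural codes", {
  tpl <- tiny_template()
  b <- add_sample(new_bundle(tpl, "p1"), "s1", list(), "water")
  b <- add_library(b, "s1", "lib1", "metagenome")
  # orphan the library, drop the ep block
  b$libraries$lib1$values$sample_name <- "ghost"
  b$eps[["ep:s1"]] <- NULL
  rep <- validate_structure(b, tpl)
  expect_true(all(c("broken_link", "missing_ep") %in% rep$code))
  # a collection the template does not define is flagged
  tpl2 <- remove_package(attach_package(tpl, collection_spec(
    "ep", "soil", list(field_definition("soil_ph", type = "decimal")))), "ep water")
  b2 <- add_sample(new_bundle(tpl, "p2"), "s1", list(), "water")
  rep2 <- validate_structure(b2, tpl2)
  expect_true("unknown_collection" %in% rep2$code)
})

test_that("the two levels are disjoint and merge additively and deterministically", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  b <- make_valid_bundle(tpl, vocabs, seed = 4, n_samples = 2)
  inj <- inject_errors(b, list(not_iso_date = 1, missing_required = 2,
                               unknown_key = 1, cv_violation = 1), seed = 9)
  v1 <- validate_values(inj$bundle, tpl, vocabs)
  v2 <- validate_structure(inj$bundle, tpl)
  vb <- validate_bundle(inj$bundle, tpl, vocabs)
  expect_length(intersect(v1$code, v2$code), 0)
  expect_equal(nrow(vb), nrow(v1) + nrow(v2))
  expect_setequal(issue_set(vb), c(issue_set(v1), issue_set(v2)))
  # byte-identical serialized reports on identical input
  expect_identical(format_report(validate_bundle(inj$bundle, tpl, vocabs), "tsv"),
                   format_report(vb, "tsv"))
})

test_that("adding a valid optional field never increases the error count", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  b <- make_valid_bundle(tpl, vocabs, seed = 6, n_samples = 2)
  inj <- inject_errors(b, list(missing_required = 1, not_iso_time = 1), seed = 2)
  before <- sum(validate_bundle(inj$bundle, tpl, vocabs)$severity == "error")
  b2 <- set_value(inj$bundle, "sample_02", "depth", "14.25")  # valid optional
  after <- sum(validate_bundle(b2, tpl, vocabs)$severity == "error")
  expect_lte(after, before)
})
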