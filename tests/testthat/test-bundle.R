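test_that("new bundles are empty and independent", {
  tpl <- tiny_template()
  b <- new_bundle(tpl, "p1")
  expect_length(b$samples, 0)
  expect_length(b$libraries, 0)
  expect_length(b$eps, 0)
  b2 <- new_bundle(tpl, "p1")
  b2 <- add_sample(b2, "s1", package = "water")
  expect_length(b$samples, 0)  # no shared state
  expect_error(new_bundle(tpl, ""), class = "mixsheet_argument_error")
})

test_that("add_sample creates the sample and its ep block atomically", {
  tpl <- tiny_template()
  b <- new_bundle(tpl, "p1")
  b <- add_sample(b, "s1", list(collection_date = "2014-01-01"), "water")
  b <- add_sample(b, "s2", list(), "water", ep_fields = list(water_temperature = "12.5"))
  expect_length(b$samples, 2)
  expect_length(b$eps, 2)
  expect_equal(b$eps[["ep:s2"]]$values$sample_name, "s2")
  expect_equal(b$eps[["ep:s2"]]$values$water_temperature, "12.5")
  expect_error(add_sample(b, "s1", list(), "water"), class = "mixsheet_conflict_error")
  expect_error(add_sample(b, "s3", list(), "lava"), class = "mixsheet_lookup_error")
})

test_that("add_library links extractions to existing samples", {
  tpl <- tiny_template()
  b <- add_sample(new_bundle(tpl, "p1"), "s1", list(), "water")
  for (i in 1:3) b <- add_library(b, "s1", paste0("lib", i), "metagenome")
  expect_length(b$libraries, 3)
  expect_true(all(vapply(b$libraries, function(e) e$values$sample_name, "") == "s1"))
  expect_error(add_library(b, "s9", "lib4", "metagenome"),
               class = "mixsheet_reference_error")
  expect_error(add_library(b, "s1", "lib1", "metagenome"),
               class = "mixsheet_conflict_error")
  # every constructive operation preserves referential integrity
  expect_true(is_valid(validate_structure(b, tpl)) ||
                all(validate_structure(b, tpl)$code != "broken_link"))
})

test_that("prefill_project copies project keys only, idempotently", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  source <- make_valid_bundle(tpl, vocabs, seed = 11, n_samples = 5)
  target <- new_bundle(tpl, "fresh")
  out <- prefill_project(source, target)
  expect_equal(out$project$values, source$project$values)
  expect_equal(out$project$id, "fresh")
  expect_length(out$samples, 0)          # project level only
  expect_length(out$libraries, 0)
  # idempotence
  expect_identical(prefill_project(source, out), out)
  # source untouched
  expect_length(source$samples, 5)
  # overwrite-on-prefill: source wins on clashing keys
  target2 <- new_bundle(tpl, "t2")
  target2 <- set_value(target2, "t2", "pi_name", "Old Name")
  expect_equal(prefill_project(source, target2)$project$values$pi_name,
               source$project$values$pi_name)
})

test_that("bundles round trip through the kv store", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  b <- make_valid_bundle(tpl, vocabs, seed = 5, n_samples = 3,
                         n_libraries_per_sample = 2)
  store <- bundle_to_store(b)
  expect_s3_class(store, "kv_store")
  b2 <- bundle_from_store(store, tpl)
  expect_true(bundle_equal(b, b2))
  # and the store itself survives its TSV dump
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kv_tsv(store, path)
  expect_true(bundle_equal(b, bundle_from_store(read_kv_tsv(path), tpl)))
})
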