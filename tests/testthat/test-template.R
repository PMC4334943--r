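test_that("a minimal template file loads as declared", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: mini",
    "version: '0.3'",
    "collections:",
    "  - name: project",
    "    fields:",
    "      - key: project_name_text",
    "        type: text",
    "        required: true",
    "  - name: sample",
    "    fields: []",
    "  - name: library",
    "    subtype: metagenome",
    "    fields: []",
    "  - name: ep",
    "    subtype: water",
    "    fields: []"), path)
  tpl <- read_template(path)
  expect_s3_class(tpl, "metadata_template")
  expect_equal(tpl$version, "0.3")
  expect_length(tpl$collections, 4)
  proj <- template_collection(tpl, "project")
  expect_length(proj$fields, 1)
  expect_true(proj$fields[[1]]$required)
})

test_that("schema violations are rejected with the offending key named", {
  expect_error(
    collection_spec("project", fields = list(
      field_definition("depth", type = "decimal"),
      field_definition("depth", type = "integer"))),
    "depth", class = "mixsheet_schema_error")
  # cv_term <=> vocab reference
  expect_error(field_definition("biome", type = "cv_term"),
               class = "mixsheet_schema_error")
  expect_error(field_definition("note", vocab = "biome"),
               class = "mixsheet_schema_error")
  # non-compiling gatekeeper is a configuration error at definition time
  expect_error(field_definition("code", type = "pattern", pattern = "(["),
               class = "mixsheet_config_error")
  # unresolved vocabulary reference at template level
  expect_error(
    metadata_template("t", collections = list(
      collection_spec("project", fields = list(
        field_definition("biome", type = "cv_term", vocab = "nope"))),
      collection_spec("sample"), collection_spec("library", "metagenome"),
      collection_spec("ep", "water")),
      vocabularies = "biome"),
    "nope", class = "mixsheet_schema_error")
  # reserved link key cannot be declared
  expect_error(
    collection_spec("library", "metagenome",
                    fields = list(field_definition("sample_name"))),
    class = "mixsheet_schema_error")
})

test_that("the bundled template has the documented collections", {
  tpl <- fx_template()
  ids <- vapply(tpl$collections, function(cs) collection_id(cs$name, cs$subtype), "")
  expect_setequal(ids, c("project", "sample", "library metagenome",
                         "ep water", "ep soil"))
})

test_that("required_fields returns required keys in declaration order", {
  tpl <- fx_template()
  # the project contact-organization key is among the required fields
  expect_true("pi_organization" %in% required_fields(tpl, "project"))
  # all-required and none-required collections
  t2 <- tiny_template()
  expect_equal(required_fields(t2, "sample"),
               c("collection_date", "latitude", "biome"))
  expect_equal(required_fields(t2, "ep water"), character(0))
  # pure function: repeated calls agree
  expect_identical(required_fields(tpl, "sample"), required_fields(tpl, "sample"))
  expect_error(required_fields(tpl, "ep lava"), class = "mixsheet_lookup_error")
})

test_that("templates round trip through their YAML serialization", {
  tpl <- fx_template()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_template(tpl, path)
  expect_identical(read_template(path), tpl)
})

test_that("attach_package composes and respects value semantics", {
  tpl <- fx_template()
  air <- read_package(system.file("extdata/templates/ep_air.yaml",
                                  package = "mixsheet"))
  tpl2 <- attach_package(tpl, air)
  ids2 <- vapply(tpl2$collections, function(cs) collection_id(cs$name, cs$subtype), "")
  expect_true(all(c("ep water", "ep air") %in% ids2))
  # input template unmodified
  expect_length(tpl$collections, 5)
  # attach then remove is the identity
  expect_identical(remove_package(tpl2, "ep air"), tpl)
  # duplicate attachment conflicts
  expect_error(attach_package(tpl2, air), class = "mixsheet_conflict_error")
  # a package referencing an unregistered vocabulary fails the invariant
  bad <- collection_spec("ep", "ice", fields = list(
    field_definition("ice_type", type = "cv_term", vocab = "cryo_terms")))
  expect_error(attach_package(tpl, bad), class = "mixsheet_schema_error")
})
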