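test_that("blank workbooks have one sheet per collection with the declared header", {
  tpl <- fx_template()
  dir <- withr::local_tempfile()
  blank_workbook(tpl, dir, "tsv-dir")
  files <- list.files(dir)
  expect_setequal(files, c("project.tsv", "sample.tsv", "library_metagenome.tsv",
                           "ep_water.tsv", "ep_soil.tsv"))
  lines <- readLines(file.path(dir, "sample.tsv"))
  expect_length(lines, 2)  # header + annotation, zero data rows
  keys <- strsplit(lines[1], "\t")[[1]]
  cs <- template_collection(tpl, "sample")
  expect_equal(keys, c("sample_name", vapply(cs$fields, `[[`, "", "key")))
  # required fields are visually marked in the annotation row
  ann <- strsplit(lines[2], "\t")[[1]]
  expect_match(ann[match("latitude", keys)], "\\*")
  expect_match(ann[match("latitude", keys)], "decimal degrees")
  # deterministic bytes: two calls, identical output
  dir2 <- withr::local_tempfile()
  blank_workbook(tpl, dir2, "tsv-dir")
  for (f in files) {
    expect_identical(readBin(file.path(dir, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
})

test_that("workbooks round trip in both dialects and agree across dialects", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  b <- make_valid_bundle(tpl, vocabs, seed = 21, n_samples = 2,
                         n_libraries_per_sample = 3)
  tsv <- withr::local_tempfile()
  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(b, tpl, tsv, "tsv-dir")
  write_workbook(b, tpl, xlsx, "xlsx")
  # 2 samples, 6 libraries as data rows
  expect_length(readLines(file.path(tsv, "sample.tsv")), 2 + 2)
  expect_length(readLines(file.path(tsv, "library_metagenome.tsv")), 2 + 6)
  rt <- read_workbook(tsv, tpl)
  rx <- read_workbook(xlsx, tpl)
  expect_equal(nrow(rt$issues), 0)
  expect_equal(nrow(rx$issues), 0)
  expect_true(bundle_equal(b, rt$bundle))
  expect_true(bundle_equal(b, rx$bundle))
  expect_true(bundle_equal(rt$bundle, rx$bundle))
})

test_that("unknown sheets warn; duplicate and blank ids are located errors", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  b <- make_valid_bundle(tpl, vocabs, seed = 22, n_samples = 2)
  dir <- withr::local_tempfile()
  write_workbook(b, tpl, dir, "tsv-dir")
  writeLines(c("note", "free text"), file.path(dir, "notes.tsv"))
  # duplicate the first sample row and add a blank-id row
  sf <- file.path(dir, "sample.tsv")
  lines <- readLines(sf)
  writeLines(c(lines, lines[3], paste0("\tstray")), sf)
  rd <- read_workbook(dir, tpl)
  expect_setequal(rd$issues$code, c("unknown_sheet", "duplicate_id", "blank_id"))
  expect_equal(rd$issues$severity[rd$issues$code == "unknown_sheet"], "warning")
  # first row wins; the stray rows were skipped
  expect_length(rd$bundle$samples, 2)
  expect_true(bundle_equal(rd$bundle, b))
  # parse issues carry sheet/row locations
  dup <- rd$issues[rd$issues$code == "duplicate_id", ]
  expect_equal(dup$sheet, "sample")
  expect_equal(dup$row, 5L)
})

test_that("empty cells are distinguishable from absent columns", {
  tpl <- tiny_template()
  b <- add_sample(new_bundle(tpl, "p1"), "s1",
                  list(collection_date = "2014-01-01"), "water")
  b <- add_sample(b, "s2",
                  list(collection_date = "2014-01-02", latitude = "10.0"), "water")
  dir <- withr::local_tempfile()
  write_workbook(b, tpl, dir, "tsv-dir")
  # both samples share the latitude column; s1's cell is simply blank
  header <- strsplit(readLines(file.path(dir, "sample.tsv"))[1], "\t")[[1]]
  expect_true("latitude" %in% header)
  rd <- read_workbook(dir, tpl)
  expect_null(rd$bundle$samples$s1$values$latitude)
  expect_equal(rd$bundle$samples$s2$values$latitude, "10.0")
})

test_that("unknown columns are preserved as extra keys through the round trip", {
  tpl <- fx_template()
  vocabs <- fx_vocabs()
  b <- make_valid_bundle(tpl, vocabs, seed = 23, n_samples = 1)
  b <- set_value(b, "sample_01", "my_custom_note", "still here")
  for (dialect in c("tsv-dir", "xlsx")) {
    path <- withr::local_tempfile(fileext = if (dialect == "xlsx") ".xlsx" else "")
    write_workbook(b, tpl, path, dialect)
    rd <- read_workbook(path, tpl, dialect)
    expect_equal(rd$bundle$samples$sample_01$values$my_custom_note, "still here")
    expect_true(bundle_equal(b, rd$bundle))
  }
})

test_that("a bundle with collections the template lacks is refused on write", {
  tpl <- fx_template()
  b <- add_sample(new_bundle(tpl, "p1"), "s1", list(), "water")
  tpl2 <- remove_package(tpl, "ep water")
  expect_error(write_workbook(b, tpl2, withr::local_tempfile(), "tsv-dir"),
               class = "mixsheet_schema_error")
})
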