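# Table-driven level-1 cases: (type, raw) -> expected issue code ("" = valid).
type_cases <- list(
  list("date", "2014-12-08", ""),
  list("date", "12/08/2014", "not_iso_date"),
  list("date", "2013-02-29", "not_iso_date"),   # not a real calendar day
  list("date", "2016-02-29", ""),               # leap year
  list("date", "20141208", "not_iso_date"),     # basic format rejected
  list("date", "2014-1-8", "not_iso_date"),     # padding required
  list("time", "09:30", ""),
  list("time", "09:30:59", ""),
  list("time", "24:00", "not_iso_time"),
  list("time", "9:30", "not_iso_time"),
  list("datetime", "2014-12-08T09:30:00", ""),
  list("datetime", "2014-12-08T09:30:00Z", ""),
  list("datetime", "2014-12-08T09:30+01:00", ""),
  list("datetime", "2014-12-08 09:30:00", "not_iso_datetime"),
  list("datetime", "2014-13-08T09:30", "not_iso_datetime"),
  list("integer", "42", ""),
  list("integer", "-7", ""),
  list("integer", "3.5", "not_integer"),
  list("integer", "4 2", "not_integer"),
  list("decimal", "3.5", ""),
  list("decimal", "-1.2e-3", ""),
  list("decimal", "3,5", "not_decimal"),        # locale commas rejected
  list("latitude", "41.88", ""),
  list("latitude", "91.0", "out_of_range"),
  list("latitude", "-90", ""),
  list("latitude", "north", "not_decimal"),
  list("longitude", "-87.63", ""),
  list("longitude", "180.0001", "out_of_range"),
  list("url", "https://example.org/x", ""),
  list("url", "example.org", "bad_url"),
  list("email", "user@example.org", ""),
  list("email", "user at example.org", "bad_email"),
  list("text", "anything at all", "")
)

test_that("values constrain to their data types", {
  for (case in type_cases) {
    f <- field_definition("f1", type = case[[1]],
                          pattern = if (case[[1]] == "pattern") ".*" else "")
    res <- validate_value(f, case[[2]])
    codes <- vapply(res$issues, `[[`, "", "code")
    if (nzchar(case[[3]])) {
      expect_equal(codes, case[[3]], info = sprintf("%s / %s", case[[1]], case[[2]]))
      expect_null(res$value)
    } else {
      expect_length(codes, 0)
      expect_false(is.null(res$value))
    }
  }
})

test_that("whitespace is trimmed and empty strings raise nothing at level 1", {
  f <- field_definition("d", type = "date", required = TRUE)
  expect_length(validate_value(f, "  2014-12-08  ")$issues, 0)
  # blank required value is level 2's business: no value, no issue here
  res <- validate_value(f, "   ")
  expect_null(res$value)
  expect_length(res$issues, 0)
})

test_that("regex gatekeepers are anchored to the full string", {
  expect_true(check_gatekeeper("[A-Z]{2}[0-9]{4}", "AB1234"))
  expect_false(check_gatekeeper("[A-Z]{2}[0-9]{4}", "AB12345"))
  expect_false(check_gatekeeper("[A-Z]{2}[0-9]{4}", "xAB1234"))
  expect_true(check_gatekeeper(".*", ""))
  # alternations cannot escape the anchoring
  expect_false(check_gatekeeper("a|b", "xa"))
  f <- field_definition("bc", type = "pattern", pattern = "[A-Z]{2}[0-9]{4}")
  expect_equal(validate_value(f, "AB12345")$issues[[1]]$code, "pattern_mismatch")
})

test_that("cv_term fields resolve against registered vocabularies only", {
  vocabs <- fx_vocabs()
  f <- field_definition("biome", type = "cv_term", vocab = "biome")
  expect_equal(validate_value(f, "Marine Biome", vocabs)$value$label, "marine biome")
  expect_equal(validate_value(f, "lava biome", vocabs)$issues[[1]]$code, "cv_violation")
  # unregistered vocabulary is a configuration error, not a validation issue
  expect_error(validate_value(f, "marine biome", list()),
               class = "mixsheet_config_error")
})

test_that("validate_value is total and deterministic on arbitrary printable input", {
  vocabs <- fx_vocabs()
  set.seed(42)
  chars <- c(letters, LETTERS, 0:9, " ", "-", ":", ".", "/", "@", "%", "+", "#")
  fields <- lapply(setdiff(data_type_tags(), c("cv_term", "pattern")), function(tp)
    field_definition("f", type = tp))
  fields <- c(fields,
              list(field_definition("f", type = "cv_term", vocab = "biome"),
                   field_definition("f", type = "pattern", pattern = "[a-z]+")))
  for (i in 1:50) {
    raw <- paste(sample(chars, sample(0:12, 1), replace = TRUE), collapse = "")
    for (f in fields) {
      r1 <- validate_value(f, raw, vocabs)
      r2 <- validate_value(f, raw, vocabs)
      expect_identical(r1, r2)
      expect_true(xor(is.null(r1$value), length(r1$issues) == 0) ||
                    (is.null(r1$value) && length(r1$issues) == 0 && !nzchar(trimws(raw))))
    }
  }
})
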