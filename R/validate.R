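#' Two-level validation
#'
#' Validation runs at two disjoint levels. Level 1 ([validate_values()])
#' checks every raw value whose key the template defines against the
#' field's data type (see [validate_value()]). Level 2
#' ([validate_structure()]) checks that the metadata structure conforms to
#' the template: required fields present and non-blank, the three-tier
#' hierarchy intact, unknown keys flagged. [validate_bundle()] is their
#' deterministic merge; by construction no issue code can be produced by
#' both levels.
#'
#' @section Issue codes:
#' \describe{
#'   \item{level 1 (error)}{`not_integer`, `not_decimal`, `not_iso_date`,
#'     `not_iso_time`, `not_iso_datetime`, `out_of_range`, `bad_url`,
#'     `bad_email`, `cv_violation`, `pattern_mismatch`}
#'   \item{level 2 (error)}{`missing_required`, `no_samples`, `missing_ep`,
#'     `broken_link`, `unknown_collection`}
#'   \item{level 2 (warning)}{`unknown_key` — extra fields are permitted,
#'     flagged, never fatal}
#'   \item{parse (from [read_workbook()])}{`unknown_sheet` (warning),
#'     `duplicate_header` (error), `blank_id` (error), `duplicate_id`
#'     (error)}
#' }
#' An empty string counts as missing for a required field (a blank cell in
#' a form is a blank cell, whatever its type), and raises no level-1 issue.
#'
#' @name validation
NULL

issue_row <- function(severity, code, entity, collection, key = "",
                      message = "", sheet = "", row = NA_integer_,
                      column = NA_integer_) {
  data.frame(severity = severity, code = code, entity = entity,
             collection = collection, key = key, sheet = sheet,
             row = as.integer(row), column = as.integer(column),
             message = message, stringsAsFactors = FALSE)
}

empty_issues <- function() issue_row(character(0), character(0), character(0),
                                     character(0), character(0), character(0),
                                     character(0), integer(0), integer(0))[0, ]

#' Assemble a validation report
#'
#' Orders issues deterministically (by collection, entity id, key, code)
#' and derives validity: a report is valid exactly when it contains no
#' issue of severity `error` (warnings do not invalidate).
#'
#' @param issues Data frame of issues (columns `severity`, `code`,
#'   `entity`, `collection`, `key`, `sheet`, `row`, `column`, `message`).
#' @return A `validation_report`: the ordered issue data frame with an
#'   `is_valid` attribute.
#' @export
validation_report <- function(issues = empty_issues()) {
  if (nrow(issues)) {
    issues <- issues[radix_order(issues$collection, issues$entity,
                                 issues$key, issues$code), , drop = FALSE]
    rownames(issues) <- NULL
  }
  structure(issues, class = c("validation_report", "data.frame"),
            is_valid = !any(issues$severity == "error"))
}

#' Is a report free of errors?
#' @param report A `validation_report`.
#' @return Logical.
#' @export
is_valid <- function(report) isTRUE(attr(report, "is_valid"))

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s)\n",
              if (is_valid(x)) "VALID" else "INVALID",
              sum(x$severity == "error"), sum(x$severity == "warning")))
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      loc <- sprintf("%s/%s", x$collection[i], x$entity[i])
      if (nzchar(x$key[i])) loc <- paste0(loc, "/", x$key[i])
      cat(sprintf("  [%s] %-18s %s: %s\n", x$severity[i], x$code[i], loc,
                  x$message[i]))
    }
  }
  invisible(x)
}

#' Serialize a report
#'
#' `tsv` is the line-oriented machine form (header + one row per issue);
#' `text` is the human form printed by the CLI.
#'
#' @param report A `validation_report`.
#' @param format `"tsv"` or `"text"`.
#' @return Character vector of lines.
#' @export
format_report <- function(report, format = c("tsv", "text")) {
  format <- match.arg(format)
  if (format == "text") {
    return(utils::capture.output(print(report)))
  }
  na2empty <- function(v) ifelse(is.na(v), "", as.character(v))
  c("severity\tcode\tentity\tcollection\tkey\tsheet\trow\tcolumn\tmessage",
    if (nrow(report)) paste(report$severity, report$code, report$entity,
                            report$collection, report$key, report$sheet,
                            na2empty(report$row), na2empty(report$column),
                            report$message, sep = "\t"))
}

#' Level-1 report: every defined value against its data type
#'
#' Checks each (entity, key, value) whose key the template defines for the
#' entity's collection. Keys the template does not know are skipped here
#' (level 2 flags them); empty values are skipped (level 2 owns
#' missingness); reserved link keys are skipped (level 2 owns the
#' hierarchy).
#'
#' @param bundle A `project_bundle`.
#' @param template The [metadata_template()] to validate against.
#' @param vocabs Named list of `controlled_vocabulary` objects covering
#'   every vocabulary the template's cv_term fields reference.
#' @return A `validation_report`.
#' @export
validate_values <- function(bundle, template, vocabs = list()) {
  stopifnot(inherits(bundle, "project_bundle"), inherits(template, "metadata_template"))
  rows <- list()
  for (e in bundle_entities(bundle)) {
    if (!has_collection(template, e$collection)) next
    cs <- template_collection(template, e$collection)
    defs <- stats::setNames(cs$fields, vapply(cs$fields, `[[`, "", "key"))
    resv <- reserved_keys(cs$name)
    for (k in names(e$values)) {
      if (k %in% resv) next
      f <- defs[[k]]
      if (is.null(f)) next
      for (v in e$values[[k]]) {
        res <- validate_value(f, v, vocabs)
        for (iss in res$issues) {
          rows[[length(rows) + 1L]] <- issue_row(
            "error", iss$code, e$id, e$collection, k, iss$message)
        }
      }
    }
  }
  validation_report(if (length(rows)) do.call(rbind, rows) else empty_issues())
}

check_entity_structure <- function(e, template, rows) {
  if (!has_collection(template, e$collection)) {
    rows[[length(rows) + 1L]] <- issue_row(
      "error", "unknown_collection", e$id, e$collection, "",
      sprintf("collection '%s' is not part of template '%s'",
              e$collection, template$name))
    return(rows)
  }
  cs <- template_collection(template, e$collection)
  keys <- vapply(cs$fields, `[[`, "", "key")
  resv <- reserved_keys(cs$name)
  for (rk in required_fields(template, e$collection)) {
    v <- e$values[[rk]]
    if (is.null(v) || all(!nzchar(trim_ws(v)))) {
      rows[[length(rows) + 1L]] <- issue_row(
        "error", "missing_required", e$id, e$collection, rk,
        sprintf("required field '%s' is absent or blank", rk))
    }
  }
  for (k in setdiff(names(e$values), c(keys, resv))) {
    rows[[length(rows) + 1L]] <- issue_row(
      "warning", "unknown_key", e$id, e$collection, k,
      sprintf("key '%s' is not part of the %s checklist (extra fields are kept, not validated)",
              k, spec_id(cs)))
  }
  rows
}

#' Level-2 report: structure against the template
#'
#' Emits `missing_required` per absent-or-blank required key per entity,
#' `unknown_key` warnings for extra keys, `no_samples` when the bundle has
#' no samples, `missing_ep` for each sample without an environmental
#' package block, `broken_link` for each library or ep block whose
#' `sample_name` names no sample, and `unknown_collection` for entities
#' whose collection the template does not define.
#'
#' @inheritParams validate_values
#' @return A `validation_report`.
#' @export
validate_structure <- function(bundle, template) {
  stopifnot(inherits(bundle, "project_bundle"), inherits(template, "metadata_template"))
  rows <- list()
  for (e in bundle_entities(bundle)) rows <- check_entity_structure(e, template, rows)
  if (length(bundle$samples) == 0L) {
    rows[[length(rows) + 1L]] <- issue_row(
      "error", "no_samples", bundle$project$id, "project", "",
      "the bundle contains no samples")
  }
  sample_ids <- names(bundle$samples)
  ep_links <- vapply(bundle$eps, function(e) {
    v <- e$values[["sample_name"]]
    if (is.null(v)) "" else v[1]
  }, "")
  for (sid in sample_ids) {
    if (!any(ep_links == sid)) {
      rows[[length(rows) + 1L]] <- issue_row(
        "error", "missing_ep", sid, "sample", "",
        sprintf("sample '%s' has no environmental package block", sid))
    }
  }
  for (e in c(unname(bundle$libraries), unname(bundle$eps))) {
    v <- e$values[["sample_name"]]
    link <- if (is.null(v)) "" else v[1]
    if (!link %in% sample_ids) {
      rows[[length(rows) + 1L]] <- issue_row(
        "error", "broken_link", e$id, e$collection, "sample_name",
        sprintf("'%s' names no sample in this bundle", link))
    }
  }
  validation_report(if (length(rows)) do.call(rbind, rows) else empty_issues())
}

#' Full validation: deterministic merge of both levels
#'
#' The two sub-reports are disjoint by construction: level 1 only emits
#' data-type codes, level 2 only structural codes.
#'
#' @inheritParams validate_values
#' @param extra_issues Optional issue data frame to merge in (e.g. parse
#'   issues from [read_workbook()]).
#' @return A `validation_report`.
#' @examples
#' tpl <- read_template(system.file("extdata/templates/mixs_core.yaml",
#'                                  package = "mixsheet"))
#' vocabs <- read_vocabulary_dir(system.file("extdata/vocab",
#'                                           package = "mixsheet"))
#' b <- make_valid_bundle(tpl, vocabs, seed = 1, n_samples = 2)
#' is_valid(validate_bundle(b, tpl, vocabs))
#' @export
validate_bundle <- function(bundle, template, vocabs = list(),
                            extra_issues = NULL) {
  v1 <- validate_values(bundle, template, vocabs)
  v2 <- validate_structure(bundle, template)
  issues <- rbind(as.data.frame(v1), as.data.frame(v2))
  if (!is.null(extra_issues) && nrow(extra_issues)) {
    issues <- rbind(issues, as.data.frame(extra_issues))
  }
  validation_report(issues)
}
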