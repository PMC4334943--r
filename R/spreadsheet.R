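#' Workbook round trip
#'
#' One sheet per collection in force, named by the collection id
#' (`project`, `sample`, `library metagenome`, `ep water`, ...). Row 1
#' holds canonical keys, row 2 human labels with units (required fields
#' marked with `*`), rows 3+ one entity per row. The first column is the
#' entity identifier (`project_name` / `sample_name` / `library_name`; on
#' ep sheets the `sample_name` link doubles as the row identifier), and
#' library sheets carry their `sample_name` link as an ordinary column.
#'
#' Two dialects are supported: `xlsx` (one Excel workbook) and `tsv-dir`
#' (a directory with one UTF-8 TSV per sheet, named like the sheet with
#' spaces replaced by underscores) for diffable, byte-deterministic output.
#' All cells are read as text: no spreadsheet-native date or number
#' coercion can mangle values before validation sees them.
#'
#' A blank cell is read as "key absent"; consequently an explicit
#' empty-string value does not survive a workbook round trip (the kvstore
#' TSV dump preserves it).
#'
#' @name spreadsheet_io
NULL

id_key_for <- function(name) {
  switch(name, project = "project_name", sample = "sample_name",
         library = "library_name", ep = "sample_name")
}

id_label_for <- function(key) {
  switch(key, project_name = "Project name *", sample_name = "Sample name *",
         library_name = "Library name *", key)
}

sheet_columns <- function(cs, entities) {
  idk <- id_key_for(cs$name)
  link <- setdiff(reserved_keys(cs$name), idk)
  keys <- vapply(cs$fields, `[[`, "", "key")
  extras <- character(0)
  for (e in entities) {
    extras <- union(extras, setdiff(names(e$values), c(idk, link, keys)))
  }
  c(idk, link, keys, extras)
}

annotation_for <- function(cs, cols) {
  keys <- vapply(cs$fields, `[[`, "", "key")
  vapply(cols, function(k) {
    i <- match(k, keys)
    if (is.na(i)) return(id_label_for(k))
    f <- cs$fields[[i]]
    lab <- f$label
    if (nzchar(f$units)) lab <- sprintf("%s (%s)", lab, f$units)
    if (f$required) lab <- paste(lab, "*")
    lab
  }, "")
}

entity_row <- function(e, cs, cols) {
  idk <- id_key_for(cs$name)
  vapply(cols, function(k) {
    if (k == idk && cs$name != "ep") return(e$id)
    v <- e$values[[k]]
    if (is.null(v)) "" else paste(v, collapse = "|")
  }, "")
}

make_sheets <- function(template, by_collection) {
  sheets <- list()
  for (cs in template$collections) {
    cid <- spec_id(cs)
    ents <- by_collection[[cid]] %||% list()
    cols <- sheet_columns(cs, ents)
    mat <- rbind(cols, annotation_for(cs, cols))
    for (e in ents) mat <- rbind(mat, entity_row(e, cs, cols))
    dimnames(mat) <- NULL
    sheets[[cid]] <- mat
  }
  sheets
}

bundle_by_collection <- function(bundle) {
  out <- list()
  for (e in bundle_entities(bundle)) {
    out[[e$collection]] <- c(out[[e$collection]], list(e))
  }
  out
}

sheet_file_name <- function(sheet) paste0(gsub(" ", "_", sheet, fixed = TRUE), ".tsv")

write_sheets_tsv_dir <- function(sheets, path) {
  if (file.exists(path) && !dir.exists(path)) {
    abort_io(sprintf("'%s' exists and is not a directory", path))
  }
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE)) {
    abort_io(sprintf("cannot create directory '%s'", path))
  }
  for (nm in names(sheets)) {
    mat <- sheets[[nm]]
    if (any(grepl("[\t\n\r]", mat))) {
      abort_argument("tsv-dir dialect does not support embedded tabs/newlines in cells")
    }
    lines <- apply(mat, 1, paste, collapse = "\t")
    con <- tryCatch(suppressWarnings(file(file.path(path, sheet_file_name(nm)), "wb")),
                    error = function(e) abort_io(sprintf("cannot write under '%s'", path)))
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  invisible(path)
}

write_sheets <- function(sheets, path, dialect) {
  switch(dialect,
    "tsv-dir" = write_sheets_tsv_dir(sheets, path),
    "xlsx" = write_xlsx_minimal(sheets, path),
    abort_argument(sprintf("unknown dialect '%s' (use 'xlsx' or 'tsv-dir')", dialect)))
}

#' Generate a blank metadata workbook from a template
#'
#' All template sheets with header and annotation rows and zero data rows.
#' For a fixed template the `tsv-dir` output is byte-identical across
#' calls, and the `xlsx` container carries a constant timestamp.
#'
#' @param template A [metadata_template()].
#' @param path Output file (`xlsx`) or directory (`tsv-dir`).
#' @param dialect `"xlsx"` or `"tsv-dir"`.
#' @return `path`, invisibly.
#' @export
blank_workbook <- function(template, path, dialect = c("xlsx", "tsv-dir")) {
  stopifnot(inherits(template, "metadata_template"))
  dialect <- match.arg(dialect)
  write_sheets(make_sheets(template, list()), path, dialect)
  invisible(path)
}

#' Write a project bundle to a workbook
#'
#' Each entity occupies one row on its collection's sheet; link keys are
#' ordinary cells; values are written as raw strings (multi-valued fields
#' pipe-joined).
#'
#' @param bundle A `project_bundle`.
#' @param template Template in force; every bundle collection must be one
#'   of its collections.
#' @inheritParams blank_workbook
#' @return `path`, invisibly.
#' @export
write_workbook <- function(bundle, template, path, dialect = c("xlsx", "tsv-dir")) {
  stopifnot(inherits(bundle, "project_bundle"), inherits(template, "metadata_template"))
  dialect <- match.arg(dialect)
  byc <- bundle_by_collection(bundle)
  unknown <- setdiff(names(byc), vapply(template$collections, spec_id, ""))
  if (length(unknown)) {
    abort_schema(sprintf("bundle uses collection '%s' which template '%s' does not define",
                         unknown[1], template$name))
  }
  write_sheets(make_sheets(template, byc), path, dialect)
  invisible(path)
}

read_sheets_tsv_dir <- function(path, expected) {
  files <- sort(list.files(path, pattern = "\\.tsv$"))
  sheets <- list(); extra <- character(0)
  lookup <- stats::setNames(expected, vapply(expected, sheet_file_name, ""))
  for (f in files) {
    lines <- readLines(file.path(path, f), encoding = "UTF-8", warn = FALSE)
    cells <- strsplit(lines, "\t", fixed = TRUE)
    ncol <- max(c(1L, lengths(cells)))
    mat <- do.call(rbind, lapply(cells, function(r) c(r, rep("", ncol - length(r)))))
    known <- f %in% names(lookup)
    nm <- if (known) lookup[[f]] else tools::file_path_sans_ext(f)
    if (!known) extra <- c(extra, nm)
    sheets[[nm]] <- mat
  }
  list(sheets = sheets, extra = extra)
}

read_sheets_xlsx <- function(path, expected) {
  names_ <- tryCatch(readxl::excel_sheets(path),
                     error = function(e) abort_io(sprintf(
                       "cannot read workbook '%s': %s", path, conditionMessage(e))))
  sheets <- list()
  for (nm in names_) {
    df <- suppressMessages(readxl::read_excel(
      path, sheet = nm, col_names = FALSE, col_types = "text",
      trim_ws = FALSE, .name_repair = "minimal"))
    mat <- as.matrix(df)
    mat[is.na(mat)] <- ""
    dimnames(mat) <- NULL
    if (length(mat) == 0L) mat <- matrix("", 0, 0)
    sheets[[nm]] <- mat
  }
  list(sheets = sheets, extra = setdiff(names_, expected))
}

parse_sheet <- function(mat, cs, sheet) {
  issues <- empty_issues()
  if (nrow(mat) < 1L) {
    return(list(entities = list(), issues = issues))
  }
  header <- trim_ws(mat[1, ])
  keep <- which(nzchar(header))
  dup <- keep[duplicated(header[keep])]
  for (j in dup) {
    issues <- rbind(issues, issue_row(
      "error", "duplicate_header", "", spec_id(cs), header[j],
      sprintf("column '%s' appears more than once; later copy ignored", header[j]),
      sheet, 1L, j))
  }
  keep <- keep[!duplicated(header[keep])]
  idk <- id_key_for(cs$name)
  idcol <- keep[header[keep] == idk]
  if (!length(idcol)) {
    issues <- rbind(issues, issue_row(
      "error", "missing_id_column", "", spec_id(cs), idk,
      sprintf("sheet '%s' has no '%s' column; sheet skipped", sheet, idk),
      sheet, 1L, NA))
    return(list(entities = list(), issues = issues))
  }
  entities <- list()
  seen <- character(0)
  if (nrow(mat) >= 3L) for (i in 3:nrow(mat)) {
    rowv <- mat[i, ]
    id <- trim_ws(rowv[idcol])
    if (!nzchar(id)) {
      if (any(nzchar(trim_ws(rowv)))) {
        issues <- rbind(issues, issue_row(
          "error", "blank_id", "", spec_id(cs), idk,
          sprintf("row %d has a blank '%s'; row skipped", i, idk),
          sheet, i, idcol))
      }
      next
    }
    eid <- if (cs$name == "ep") paste0("ep:", id) else id
    if (eid %in% seen || (cs$name == "project" && length(entities))) {
      issues <- rbind(issues, issue_row(
        "error", "duplicate_id", eid, spec_id(cs), idk,
        sprintf("row %d repeats identifier '%s'; first row wins, this row skipped", i, id),
        sheet, i, idcol))
      next
    }
    seen <- c(seen, eid)
    values <- list()
    for (j in keep) {
      if (j == idcol && cs$name != "ep") next
      v <- rowv[j]
      if (is.na(v) || !nzchar(v)) next
      values[[header[j]]] <- v
    }
    if (cs$name == "ep" && is.null(values[["sample_name"]])) {
      values[["sample_name"]] <- id
    }
    entities[[eid]] <- new_entity(eid, spec_id(cs), values)
  }
  list(entities = entities, issues = issues)
}

#' Read a metadata workbook back into a bundle
#'
#' Best-effort: unknown sheets are warnings and are skipped, rows with a
#' blank identifier are skipped with an error recorded, the first of two
#' rows sharing an identifier wins. Every parse issue carries its sheet,
#' row and column. Parse issues are distinct from validation: pass the
#' returned bundle (and issues, via `extra_issues`) to [validate_bundle()].
#'
#' @param path Workbook file (`xlsx`) or directory (`tsv-dir`); the dialect
#'   is inferred from what `path` is, unless given.
#' @param template Template describing the expected sheets.
#' @param dialect `"xlsx"`, `"tsv-dir"`, or `NULL` to infer.
#' @return List with elements `bundle` (a `project_bundle`) and `issues`
#'   (issue data frame as in [validation_report()]).
#' @export
read_workbook <- function(path, template, dialect = NULL) {
  stopifnot(inherits(template, "metadata_template"))
  if (is.null(dialect)) dialect <- if (dir.exists(path)) "tsv-dir" else "xlsx"
  if (!file.exists(path)) abort_io(sprintf("workbook '%s' does not exist", path))
  expected <- vapply(template$collections, spec_id, "")
  got <- switch(dialect,
    "tsv-dir" = read_sheets_tsv_dir(path, expected),
    "xlsx" = read_sheets_xlsx(path, expected),
    abort_argument(sprintf("unknown dialect '%s'", dialect)))
  issues <- empty_issues()
  for (nm in got$extra) {
    issues <- rbind(issues, issue_row(
      "warning", "unknown_sheet", "", nm, "",
      sprintf("sheet '%s' matches no template collection; ignored", nm), nm))
  }
  parsed <- list()
  for (cs in template$collections) {
    cid <- spec_id(cs)
    if (is.null(got$sheets[[cid]])) next
    p <- parse_sheet(got$sheets[[cid]], cs, cid)
    issues <- rbind(issues, p$issues)
    parsed[[cid]] <- p$entities
  }
  projects <- parsed[["project"]] %||% list()
  if (length(projects)) {
    bundle <- new_bundle(template, projects[[1]]$id)
    bundle$project <- projects[[1]]
  } else {
    issues <- rbind(issues, issue_row(
      "error", "missing_project", "", "project", "",
      "workbook has no project row; placeholder project used", "project"))
    bundle <- new_bundle(template, "unnamed-project")
  }
  for (cs in template$collections) {
    cid <- spec_id(cs)
    for (e in parsed[[cid]] %||% list()) {
      if (cs$name == "sample") bundle$samples[[e$id]] <- e
      else if (cs$name == "library") bundle$libraries[[e$id]] <- e
      else if (cs$name == "ep") bundle$eps[[e$id]] <- e
    }
  }
  list(bundle = bundle, issues = issues)
}
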