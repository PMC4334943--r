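#' Metadata templates: checklists and environmental packages as data
#'
#' A metadata template bundles the per-collection field contracts for one
#' submission standard: exactly one `project` collection, one `sample`
#' collection, at least one `library` collection (one per library type) and
#' at least one `ep` (environmental package) collection. Templates live in
#' YAML files (see `inst/docs/template-format.md`) so that standards are
#' data, not code: swapping or extending a checklist never requires a code
#' change.
#'
#' Each field carries a data-type tag drawn from the closed set
#' `data_type_tags()`. `cv_term` fields must name a vocabulary registered
#' with the template; `pattern` fields must carry a regular expression that
#' compiles at load time.
#'
#' @name metadata_template
NULL

#' Data type tags understood by the validator
#'
#' @return Character vector of the twelve recognised tags.
#' @export
data_type_tags <- function() {
  c("text", "integer", "decimal", "date", "time", "datetime",
    "latitude", "longitude", "url", "email", "cv_term", "pattern")
}

#' Reserved link keys
#'
#' `sample_name` inside a library or ep entity links the child to its sample.
#' Reserved keys are handled by the hierarchy checks, never flagged as
#' unknown, and never declared in a template.
#' @return Named list: for each collection name, its reserved keys.
#' @keywords internal
reserved_keys <- function(collection_name) {
  switch(collection_name,
    library = "sample_name",
    ep = "sample_name",
    character(0)
  )
}

#' Construct a field definition
#'
#' @param key Canonical token: lowercase, underscore-separated.
#' @param label Display label (original casing); defaults to `key`.
#' @param type One of [data_type_tags()].
#' @param required Logical; is the field mandatory in its collection?
#' @param definition Free-text definition.
#' @param vocab Vocabulary name (required iff `type = "cv_term"`).
#' @param pattern Regex source (required iff `type = "pattern"`),
#'   full-string anchored at check time.
#' @param units Unit string, or `""`.
#' @param example Example value, or `""`. For `pattern` fields the synthetic
#'   generator uses the example as its valid value.
#' @param multi Logical; may the field hold several values per entity?
#' @return A `field_definition` object.
#' @export
field_definition <- function(key, label = key, type = "text",
                             required = FALSE, definition = "",
                             vocab = "", pattern = "", units = "",
                             example = "", multi = FALSE) {
  key <- as.character(key)
  if (!nzchar(key) || !grepl("^[a-z0-9_]+$", key)) {
    abort_schema(sprintf(
      "field key '%s' is not a canonical token (lowercase, digits, underscores)", key))
  }
  type <- as.character(type)
  if (!type %in% data_type_tags()) {
    abort_schema(sprintf("field '%s': unknown data type tag '%s'", key, type))
  }
  vocab <- as.character(vocab %||% "")
  pattern <- as.character(pattern %||% "")
  if ((type == "cv_term") != nzchar(vocab)) {
    abort_schema(sprintf(
      "field '%s': a vocabulary reference is required exactly when type is cv_term", key))
  }
  if (type == "pattern") {
    if (!nzchar(pattern)) {
      abort_schema(sprintf("field '%s': type pattern requires a regex", key))
    }
    ok <- tryCatch({ grepl(pattern, "x"); TRUE }, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) abort_config(sprintf("field '%s': regex '%s' does not compile", key, pattern))
  }
  structure(list(
    key = key, label = as.character(label %||% key),
    definition = as.character(definition %||% ""), type = type,
    required = isTRUE(required), vocab = vocab, pattern = pattern,
    units = as.character(units %||% ""), example = as.character(example %||% ""),
    multi = isTRUE(multi)
  ), class = "field_definition")
}

#' Construct a collection specification
#'
#' @param name One of `"project"`, `"sample"`, `"library"`, `"ep"`.
#' @param subtype Free tag (library type or package name). Mandatory for
#'   `library` and `ep` collections; must not contain spaces or underscores
#'   (sheet/file naming relies on this).
#' @param fields List of [field_definition()]s, order-significant.
#' @return A `collection_spec` object.
#' @export
collection_spec <- function(name, subtype = "", fields = list()) {
  name <- as.character(name)
  if (!name %in% c("project", "sample", "library", "ep")) {
    abort_schema(sprintf("unknown collection name '%s'", name))
  }
  subtype <- as.character(subtype %||% "")
  if (name %in% c("library", "ep") && !nzchar(subtype)) {
    abort_schema(sprintf("%s collections require a subtype", name))
  }
  if (name %in% c("project", "sample") && nzchar(subtype)) {
    abort_schema(sprintf("%s collections take no subtype", name))
  }
  if (grepl("[ _]", subtype)) {
    abort_schema(sprintf("subtype '%s' must not contain spaces or underscores", subtype))
  }
  fields <- lapply(fields, function(f) {
    if (inherits(f, "field_definition")) f else do.call(field_definition, f)
  })
  keys <- vapply(fields, `[[`, "", "key")
  if (anyDuplicated(keys)) {
    abort_schema(sprintf("duplicate field key '%s' in collection %s",
                         keys[duplicated(keys)][1], collection_id(name, subtype)))
  }
  rk <- intersect(keys, reserved_keys(name))
  if (length(rk)) {
    abort_schema(sprintf("key '%s' is reserved in %s collections", rk[1], name))
  }
  structure(list(name = name, subtype = subtype, fields = fields),
            class = "collection_spec")
}

#' Canonical collection identifier
#'
#' `"project"`, `"sample"`, `"library metagenome"`, `"ep water"`, ... Also
#' the sheet name of the collection in a workbook.
#' @param name Collection name.
#' @param subtype Collection subtype or `""`.
#' @return A single string.
#' @export
collection_id <- function(name, subtype = "") {
  if (nzchar(subtype)) paste(name, subtype) else name
}

spec_id <- function(spec) collection_id(spec$name, spec$subtype)

#' Construct and check a metadata template
#'
#' Enforces the template invariants: exactly one project and one sample
#' collection, at least one library and one ep collection, no duplicate
#' (name, subtype) pairs, and every `cv_term` vocabulary reference resolving
#' against the registered vocabulary names.
#'
#' @param name Template name.
#' @param version Template version string.
#' @param collections List of [collection_spec()]s.
#' @param vocabularies Character vector of registered vocabulary names.
#' @return A `metadata_template` object.
#' @export
metadata_template <- function(name, version = "1.0", collections = list(),
                              vocabularies = character(0)) {
  collections <- lapply(collections, function(cs) {
    if (inherits(cs, "collection_spec")) cs else do.call(collection_spec, cs)
  })
  ids <- vapply(collections, spec_id, "")
  if (anyDuplicated(ids)) {
    abort_conflict(sprintf("duplicate collection '%s'", ids[duplicated(ids)][1]))
  }
  nms <- vapply(collections, `[[`, "", "name")
  if (sum(nms == "project") != 1) abort_schema("template needs exactly one project collection")
  if (sum(nms == "sample") != 1) abort_schema("template needs exactly one sample collection")
  if (!any(nms == "library")) abort_schema("template needs at least one library collection")
  if (!any(nms == "ep")) abort_schema("template needs at least one ep collection")
  vocabularies <- as.character(vocabularies)
  for (cs in collections) {
    for (f in cs$fields) {
      if (f$type == "cv_term" && !f$vocab %in% vocabularies) {
        abort_schema(sprintf(
          "field '%s' in %s references unregistered vocabulary '%s'",
          f$key, spec_id(cs), f$vocab))
      }
    }
  }
  structure(list(name = as.character(name), version = as.character(version),
                 vocabularies = vocabularies, collections = collections),
            class = "metadata_template")
}

#' @export
print.metadata_template <- function(x, ...) {
  cat(sprintf("<metadata_template> %s (version %s)\n", x$name, x$version))
  for (cs in x$collections) {
    req <- sum(vapply(cs$fields, `[[`, TRUE, "required"))
    cat(sprintf("  %-24s %d fields (%d required)\n", spec_id(cs),
                length(cs$fields), req))
  }
  if (length(x$vocabularies)) {
    cat("  vocabularies:", paste(x$vocabularies, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.collection_spec <- function(x, ...) {
  cat(sprintf("<collection_spec> %s: %d fields\n", spec_id(x), length(x$fields)))
  invisible(x)
}

field_from_yaml <- function(entry, where) {
  if (!is.list(entry) || is.null(entry$key)) {
    abort_parse(sprintf("malformed field entry in %s: every field needs a 'key'", where))
  }
  known <- c("key", "label", "definition", "type", "required", "vocab",
             "pattern", "units", "example", "multi")
  extra <- setdiff(names(entry), known)
  if (length(extra)) {
    abort_parse(sprintf("unknown field attribute '%s' for key '%s' in %s",
                        extra[1], entry$key, where))
  }
  field_definition(
    key = entry$key, label = entry$label %||% entry$key,
    type = as.character(entry$type %||% "text"),
    required = isTRUE(entry$required),
    definition = entry$definition %||% "", vocab = entry$vocab %||% "",
    pattern = entry$pattern %||% "", units = entry$units %||% "",
    example = as.character(entry$example %||% ""), multi = isTRUE(entry$multi)
  )
}

collection_from_yaml <- function(entry, where) {
  if (!is.list(entry) || is.null(entry$name)) {
    abort_parse(sprintf("malformed collection entry in %s: missing 'name'", where))
  }
  cid <- collection_id(as.character(entry$name), as.character(entry$subtype %||% ""))
  fields <- lapply(entry$fields %||% list(), field_from_yaml,
                   where = sprintf("%s collection '%s'", where, cid))
  collection_spec(entry$name, entry$subtype %||% "", fields)
}

parse_template_yaml <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_parse(sprintf(
                    "cannot parse template file '%s': %s", path, conditionMessage(e))))
  if (!is.list(doc)) abort_parse(sprintf("template file '%s' is not a mapping", path))
  doc
}

#' Load a metadata template from a YAML file
#'
#' @param path Path to a template file in the documented format
#'   (`inst/docs/template-format.md`). The bundled example lives at
#'   `system.file("extdata/templates/mixs_core.yaml", package = "mixsheet")`.
#' @return A [metadata_template()] object; loading is pure (no global state).
#' @examples
#' tpl <- read_template(system.file("extdata/templates/mixs_core.yaml",
#'                                  package = "mixsheet"))
#' required_fields(tpl, "project")
#' @export
read_template <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("template file '%s' does not exist", path))
  doc <- parse_template_yaml(path)
  for (fld in c("name", "collections")) {
    if (is.null(doc[[fld]])) {
      abort_parse(sprintf("template file '%s' is missing '%s'", path, fld))
    }
  }
  collections <- lapply(doc$collections, collection_from_yaml, where = path)
  metadata_template(name = doc$name, version = as.character(doc$version %||% "1.0"),
                    collections = collections,
                    vocabularies = as.character(unlist(doc$vocabularies %||% list())))
}

#' Write a metadata template to a YAML file
#'
#' `read_template(write_template(t, path))` reproduces `t` field for field.
#' @param template A [metadata_template()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "metadata_template"))
  doc <- list(
    name = template$name, version = template$version,
    vocabularies = as.list(template$vocabularies),
    collections = lapply(template$collections, function(cs) {
      entry <- list(name = cs$name)
      if (nzchar(cs$subtype)) entry$subtype <- cs$subtype
      entry$fields <- lapply(cs$fields, function(f) {
        out <- list(key = f$key, label = f$label, type = f$type)
        if (f$required) out$required <- TRUE
        if (nzchar(f$definition)) out$definition <- f$definition
        if (nzchar(f$vocab)) out$vocab <- f$vocab
        if (nzchar(f$pattern)) out$pattern <- f$pattern
        if (nzchar(f$units)) out$units <- f$units
        if (nzchar(f$example)) out$example <- f$example
        if (f$multi) out$multi <- TRUE
        out
      })
      entry
    })
  )
  ok <- tryCatch({ yaml::write_yaml(doc, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write template to '%s'", path))
  invisible(path)
}

#' Look up one collection of a template
#'
#' @param template A [metadata_template()].
#' @param collection Collection identifier, e.g. `"sample"` or `"ep water"`.
#' @return The matching `collection_spec`.
#' @export
template_collection <- function(template, collection) {
  stopifnot(inherits(template, "metadata_template"))
  ids <- vapply(template$collections, spec_id, "")
  i <- match(collection, ids)
  if (is.na(i)) {
    abort_lookup(sprintf("template '%s' has no collection '%s' (has: %s)",
                         template$name, collection, paste(ids, collapse = ", ")))
  }
  template$collections[[i]]
}

has_collection <- function(template, collection) {
  collection %in% vapply(template$collections, spec_id, "")
}

#' Required field keys of a collection, in declaration order
#'
#' @inheritParams template_collection
#' @return Character vector of the keys whose `required` flag is set.
#' @export
required_fields <- function(template, collection) {
  cs <- template_collection(template, collection)
  keys <- vapply(cs$fields, `[[`, "", "key")
  keys[vapply(cs$fields, `[[`, TRUE, "required")]
}

#' Read a pluggable package file
#'
#' A package file is a template-format YAML document whose `collections`
#' entry holds the packages to plug in (usually a single `ep` collection);
#' its `vocabularies` entry lists any vocabulary names the package needs
#' registered.
#'
#' @param path Path to the package file.
#' @return List with elements `collections` (list of `collection_spec`) and
#'   `vocabularies` (character).
#' @export
read_package <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("package file '%s' does not exist", path))
  doc <- parse_template_yaml(path)
  if (is.null(doc$collections)) {
    abort_parse(sprintf("package file '%s' is missing 'collections'", path))
  }
  list(collections = lapply(doc$collections, collection_from_yaml, where = path),
       vocabularies = as.character(unlist(doc$vocabularies %||% list())))
}

#' Attach an environmental package (or library type) to a template
#'
#' Returns a new template containing the extra collection; the input
#' template is unmodified (value semantics).
#'
#' @param template A [metadata_template()].
#' @param package A `collection_spec` (typically `name = "ep"`), or the
#'   result of [read_package()], or a path to a package file.
#' @param vocabularies Extra vocabulary names to register alongside.
#' @return The extended `metadata_template`.
#' @export
attach_package <- function(template, package, vocabularies = character(0)) {
  stopifnot(inherits(template, "metadata_template"))
  if (is.character(package) && length(package) == 1L) package <- read_package(package)
  if (inherits(package, "collection_spec")) {
    package <- list(collections = list(package), vocabularies = character(0))
  }
  ids <- vapply(template$collections, spec_id, "")
  for (cs in package$collections) {
    if (spec_id(cs) %in% ids) {
      abort_conflict(sprintf("collection '%s' is already present", spec_id(cs)))
    }
  }
  metadata_template(
    name = template$name, version = template$version,
    collections = c(template$collections, package$collections),
    vocabularies = union(template$vocabularies,
                         c(package$vocabularies, vocabularies))
  )
}

#' Remove a collection from a template
#'
#' Inverse of [attach_package()]: `remove_package(attach_package(t, p), id)`
#' equals `t` up to the vocabulary registry.
#'
#' @inheritParams template_collection
#' @return The reduced `metadata_template`.
#' @export
remove_package <- function(template, collection) {
  stopifnot(inherits(template, "metadata_template"))
  ids <- vapply(template$collections, spec_id, "")
  i <- match(collection, ids)
  if (is.na(i)) abort_lookup(sprintf("no collection '%s' to remove", collection))
  metadata_template(template$name, template$version,
                    template$collections[-i], template$vocabularies)
}
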