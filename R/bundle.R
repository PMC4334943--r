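#' Project bundles: the three-tier hierarchy
#'
#' A bundle models one study: a single project entity, any number of
#' sample entities, any number of library ("extraction") entities per
#' sample, and exactly one environmental-package (ep) block per sample.
#' Libraries and ep blocks link to their sample through the reserved
#' `sample_name` key, mirroring flat-spreadsheet practice.
#'
#' Bundles built through [new_bundle()], [add_sample()] and [add_library()]
#' always satisfy referential integrity; bundles read back from an edited
#' workbook may not, which is precisely what [validate_structure()] reports
#' (`broken_link`, `missing_ep`, `no_samples`).
#'
#' @name project_bundle
NULL

#' Create an empty project bundle
#'
#' @param template The [metadata_template()] in force; operations use it to
#'   check package and library subtypes.
#' @param project_id Non-empty project identifier.
#' @return A `project_bundle` with an empty project entity and no samples,
#'   libraries or ep blocks.
#' @export
new_bundle <- function(template, project_id) {
  stopifnot(inherits(template, "metadata_template"))
  project_id <- as.character(project_id)
  if (length(project_id) != 1L || !nzchar(project_id)) {
    abort_argument("project_id must be a non-empty string")
  }
  structure(list(
    template = template,
    project = new_entity(project_id, "project"),
    samples = list(), libraries = list(), eps = list()
  ), class = "project_bundle")
}

bundle_ids <- function(bundle) {
  c(bundle$project$id,
    vapply(bundle$samples, `[[`, "", "id"),
    vapply(bundle$libraries, `[[`, "", "id"),
    vapply(bundle$eps, `[[`, "", "id"))
}

as_value_list <- function(fields) {
  if (length(fields) == 0L) return(list())
  stopifnot(!is.null(names(fields)), all(nzchar(names(fields))))
  lapply(as.list(fields), as.character)
}

#' Add a sample (with its environmental-package block)
#'
#' The sample entity and its ep block are created atomically; the ep block
#' is created under collection `"ep <package>"` with its `sample_name` link
#' set, and may start out empty of descriptive fields.
#'
#' @param bundle A `project_bundle`.
#' @param sample_id New, unused entity id.
#' @param fields Named list/character of sample key-value pairs.
#' @param package Environmental package subtype (e.g. `"water"`); must be a
#'   known `ep` collection of the bundle's template.
#' @param ep_fields Named list of values for the ep block.
#' @return The updated bundle.
#' @export
add_sample <- function(bundle, sample_id, fields = list(), package,
                       ep_fields = list()) {
  stopifnot(inherits(bundle, "project_bundle"))
  sample_id <- as.character(sample_id)
  if (length(sample_id) != 1L || !nzchar(sample_id)) {
    abort_argument("sample_id must be a non-empty string")
  }
  if (sample_id %in% bundle_ids(bundle)) {
    abort_conflict(sprintf("entity id '%s' is already used in this bundle", sample_id))
  }
  ep_col <- collection_id("ep", package)
  if (!has_collection(bundle$template, ep_col)) {
    abort_lookup(sprintf("template '%s' knows no environmental package '%s'",
                         bundle$template$name, package))
  }
  ep_id <- paste0("ep:", sample_id)
  if (ep_id %in% bundle_ids(bundle)) {
    abort_conflict(sprintf("entity id '%s' is already used in this bundle", ep_id))
  }
  bundle$samples[[sample_id]] <- new_entity(sample_id, "sample", as_value_list(fields))
  bundle$eps[[ep_id]] <- new_entity(
    ep_id, ep_col, c(list(sample_name = sample_id), as_value_list(ep_fields)))
  bundle
}

#' Add a sequencing library ("extraction") to a sample
#'
#' @param bundle A `project_bundle`.
#' @param sample_id Id of an existing sample.
#' @param library_id New, unused entity id.
#' @param subtype Library type (e.g. `"metagenome"`); must be a known
#'   `library` collection of the template.
#' @param fields Named list of library key-value pairs.
#' @return The updated bundle.
#' @export
add_library <- function(bundle, sample_id, library_id, subtype = "metagenome",
                        fields = list()) {
  stopifnot(inherits(bundle, "project_bundle"))
  sample_id <- as.character(sample_id); library_id <- as.character(library_id)
  if (!sample_id %in% names(bundle$samples)) {
    abort_reference(sprintf("no sample '%s' in this bundle", sample_id))
  }
  if (length(library_id) != 1L || !nzchar(library_id)) {
    abort_argument("library_id must be a non-empty string")
  }
  if (library_id %in% bundle_ids(bundle)) {
    abort_conflict(sprintf("entity id '%s' is already used in this bundle", library_id))
  }
  lib_col <- collection_id("library", subtype)
  if (!has_collection(bundle$template, lib_col)) {
    abort_lookup(sprintf("template '%s' knows no library type '%s'",
                         bundle$template$name, subtype))
  }
  bundle$libraries[[library_id]] <- new_entity(
    library_id, lib_col, c(list(sample_name = sample_id), as_value_list(fields)))
  bundle
}

#' Copy project-level metadata from one bundle into another
#'
#' Every project key present in `source` is copied into `target`'s project
#' entity, overwriting existing values (the stored project wins, as when
#' saved information prefills a fresh form). Samples, libraries and ep
#' blocks of `target` are untouched; `source` is unmodified. Idempotent.
#'
#' @param source Bundle providing project values.
#' @param target Bundle receiving them.
#' @return The updated `target`.
#' @export
prefill_project <- function(source, target) {
  stopifnot(inherits(source, "project_bundle"), inherits(target, "project_bundle"))
  for (k in names(source$project$values)) {
    target$project$values[[k]] <- source$project$values[[k]]
  }
  target
}

find_entity <- function(bundle, id) {
  if (bundle$project$id == id) return(list(tier = "project", entity = bundle$project))
  if (id %in% names(bundle$samples)) return(list(tier = "samples", entity = bundle$samples[[id]]))
  if (id %in% names(bundle$libraries)) return(list(tier = "libraries", entity = bundle$libraries[[id]]))
  if (id %in% names(bundle$eps)) return(list(tier = "eps", entity = bundle$eps[[id]]))
  NULL
}

#' Set (or add) one value on an entity of a bundle
#'
#' Low-level editing helper used by the synthetic corruption injector and
#' by tests; looks the entity up by id across all four tiers.
#'
#' @param bundle A `project_bundle`.
#' @param id Entity id.
#' @param key Key to set.
#' @param value New raw string value.
#' @return The updated bundle.
#' @export
set_value <- function(bundle, id, key, value) {
  hit <- find_entity(bundle, id)
  if (is.null(hit)) abort_lookup(sprintf("no entity '%s' in this bundle", id))
  if (hit$tier == "project") {
    bundle$project$values[[key]] <- as.character(value)
  } else {
    bundle[[hit$tier]][[id]]$values[[key]] <- as.character(value)
  }
  bundle
}

drop_entity <- function(bundle, id) {
  hit <- find_entity(bundle, id)
  if (is.null(hit) || hit$tier == "project") {
    abort_lookup(sprintf("cannot drop entity '%s'", id))
  }
  bundle[[hit$tier]][[id]] <- NULL
  bundle
}

bundle_entities <- function(bundle) {
  c(list(bundle$project), unname(bundle$samples),
    unname(bundle$libraries), unname(bundle$eps))
}

#' Flatten a bundle to its key-value records
#'
#' @param bundle A `project_bundle`.
#' @return A `kv_store` holding one record per (entity, key, value).
#' @export
bundle_to_store <- function(bundle) {
  stopifnot(inherits(bundle, "project_bundle"))
  kv_from_entities(bundle_entities(bundle))
}

#' Rebuild a bundle from key-value records
#'
#' Entities are recognised by collection: `project`, `sample`,
#' `library <subtype>` and `ep <package>`. An entity with no records cannot
#' be reconstructed (nothing marks its existence in the flat table).
#'
#' @param store A `kv_store`.
#' @param template Template to associate with the bundle.
#' @return A `project_bundle`.
#' @export
bundle_from_store <- function(store, template) {
  stopifnot(inherits(store, "kv_store"), inherits(template, "metadata_template"))
  ents <- kv_entities(store)
  cols <- vapply(ents, `[[`, "", "collection")
  proj <- ents[cols == "project"]
  if (length(proj) == 0L) abort_parse("store holds no project entity")
  if (length(proj) > 1L) abort_parse("store holds more than one project entity")
  b <- new_bundle(template, proj[[1]]$id)
  b$project <- proj[[1]]
  for (e in ents[cols == "sample"]) b$samples[[e$id]] <- e
  for (e in ents[startsWith(cols, "library ")]) b$libraries[[e$id]] <- e
  for (e in ents[startsWith(cols, "ep ")]) b$eps[[e$id]] <- e
  b
}

norm_entity <- function(e) {
  v <- e$values
  v <- v[radix_order(names(v))]
  list(id = e$id, collection = e$collection, values = v)
}

#' Compare two bundles for metadata equality
#'
#' Entities are matched by id; value maps are compared irrespective of key
#' order; the associated templates are not compared.
#'
#' @param a,b `project_bundle` objects.
#' @return `TRUE` or `FALSE`.
#' @export
bundle_equal <- function(a, b) {
  stopifnot(inherits(a, "project_bundle"), inherits(b, "project_bundle"))
  norm <- function(x) {
    ents <- bundle_entities(x)
    ents <- ents[radix_order(vapply(ents, `[[`, "", "id"))]
    lapply(ents, norm_entity)
  }
  isTRUE(all.equal(norm(a), norm(b)))
}

#' @export
print.project_bundle <- function(x, ...) {
  cat(sprintf("<project_bundle> project '%s': %d samples, %d libraries, %d ep blocks\n",
              x$project$id, length(x$samples), length(x$libraries), length(x$eps)))
  invisible(x)
}
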