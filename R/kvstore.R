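#' Entity-attribute-value store
#'
#' The storage model is a single flat table with four columns,
#' `id | collection | key | value`: arbitrary key-value pairs on any entity,
#' optionally organised into collections whose field contracts a template
#' supplies. Values are raw strings; typed interpretation happens only at
#' validation time. Stores have value semantics: `kv_put()` returns an
#' updated copy.
#'
#' @name kvstore
NULL

#' Create an empty key-value store
#' @return A `kv_store` object.
#' @export
kv_store <- function() {
  structure(list(records = data.frame(
    id = character(0), collection = character(0),
    key = character(0), value = character(0),
    stringsAsFactors = FALSE)), class = "kv_store")
}

#' Insert or replace a value
#'
#' By default a triple `(id, collection, key)` is single-valued: a second
#' put replaces the first. With `multi = TRUE` the value is appended,
#' for fields declared multi-valued.
#'
#' @param store A `kv_store`.
#' @param id Entity identifier (non-empty).
#' @param collection Collection identifier, e.g. `"sample"` or `"ep water"`.
#' @param key Canonical key (non-empty).
#' @param value Raw string value (an empty string is a value, not absence).
#' @param multi Append instead of replace.
#' @return The updated `kv_store`.
#' @export
kv_put <- function(store, id, collection, key, value, multi = FALSE) {
  stopifnot(inherits(store, "kv_store"))
  id <- as.character(id); key <- as.character(key)
  collection <- as.character(collection); value <- as.character(value)
  if (length(id) != 1L || !nzchar(id)) abort_argument("entity id must be a non-empty string")
  if (length(key) != 1L || !nzchar(key)) abort_argument("key must be a non-empty string")
  rec <- store$records
  if (!multi) {
    drop <- rec$id == id & rec$collection == collection & rec$key == key
    if (any(drop)) {
      # replace in place, preserving the record's position
      rec$value[which(drop)[1]] <- value
      if (sum(drop) > 1L) rec <- rec[!drop | cumsum(drop) == 1L, ]
      store$records <- rec
      return(store)
    }
  }
  store$records <- rbind(rec, data.frame(
    id = id, collection = collection, key = key, value = value,
    stringsAsFactors = FALSE))
  store
}

#' Retrieve a value
#'
#' Absence is reported as `NULL`, distinguishable from a stored empty
#' string; absence is a value, not an error.
#'
#' @inheritParams kv_put
#' @return Character vector of stored value(s), or `NULL` if never written.
#' @export
kv_get <- function(store, id, collection, key) {
  stopifnot(inherits(store, "kv_store"))
  rec <- store$records
  hit <- rec$id == id & rec$collection == collection & rec$key == key
  if (!any(hit)) return(NULL)
  rec$value[hit]
}

new_entity <- function(id, collection, values = list()) {
  structure(list(id = as.character(id), collection = as.character(collection),
                 values = values), class = "mx_entity")
}

#' @export
print.mx_entity <- function(x, ...) {
  cat(sprintf("<entity> %s [%s]: %d keys\n", x$id, x$collection, length(x$values)))
  invisible(x)
}

#' List entities, grouped from the flat record table
#'
#' An entity is exactly the set of records sharing `(id, collection)`, with
#' values in first-put order. Entities are returned sorted by id
#' (byte-wise lexicographic), so the listing is deterministic.
#'
#' @param store A `kv_store`.
#' @param collection Restrict to one collection, or `NULL` for all.
#' @return List of entity objects (`id`, `collection`, `values`).
#' @export
kv_entities <- function(store, collection = NULL) {
  stopifnot(inherits(store, "kv_store"))
  rec <- store$records
  if (!is.null(collection)) rec <- rec[rec$collection == collection, , drop = FALSE]
  if (nrow(rec) == 0L) return(list())
  grp <- paste0(rec$collection, "\r", rec$id)
  out <- lapply(split(seq_len(nrow(rec)), grp), function(idx) {
    vals <- split(rec$value[idx], factor(rec$key[idx], levels = unique(rec$key[idx])))
    new_entity(rec$id[idx[1]], rec$collection[idx[1]], as.list(vals))
  })
  ids <- vapply(out, `[[`, "", "id")
  cols <- vapply(out, `[[`, "", "collection")
  unname(out[radix_order(cols, ids)])
}

#' Rebuild a store from entities
#'
#' Inverse of [kv_entities()]: the multiset of records is conserved.
#'
#' @param entities List of entity objects.
#' @return A `kv_store`.
#' @export
kv_from_entities <- function(entities) {
  store <- kv_store()
  recs <- lapply(entities, function(e) {
    if (length(e$values) == 0L) return(NULL)
    data.frame(id = e$id, collection = e$collection,
               key = rep(names(e$values), lengths(e$values)),
               value = unlist(e$values, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs)) store$records <- do.call(rbind, recs)
  store
}

#' Dump a store to the four-column TSV form
#'
#' Columns `id`, `collection`, `key`, `value`; UTF-8, header row, one
#' record per line. Values must not contain tabs or newlines.
#'
#' @param store A `kv_store`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kv_tsv <- function(store, path) {
  stopifnot(inherits(store, "kv_store"))
  rec <- store$records
  bad <- grepl("[\t\n\r]", rec$value) | grepl("[\t\n\r]", rec$key)
  if (any(bad)) abort_argument("TSV serialization does not support embedded tabs/newlines")
  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e) abort_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeLines(c("id\tcollection\tkey\tvalue",
               paste(rec$id, rec$collection, rec$key, rec$value, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Load a store from its TSV dump
#'
#' @param path Path to a four-column TSV written by [write_kv_tsv()].
#' @return A `kv_store`.
#' @export
read_kv_tsv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("store file '%s' does not exist", path))
  df <- tryCatch(
    utils::read.delim(path, colClasses = "character", sep = "\t", quote = "",
                      fileEncoding = "UTF-8", check.names = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse store file '%s': %s",
                                            path, conditionMessage(e))))
  if (!all(c("id", "collection", "key", "value") %in% names(df))) {
    abort_parse(sprintf("store file '%s' lacks the id/collection/key/value columns", path))
  }
  store <- kv_store()
  store$records <- df[, c("id", "collection", "key", "value")]
  rownames(store$records) <- NULL
  store
}

#' @export
print.kv_store <- function(x, ...) {
  cat(sprintf("<kv_store> %d records, %d entities\n",
              nrow(x$records),
              nrow(unique(x$records[, c("id", "collection")]))))
  invisible(x)
}
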