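#' Controlled vocabularies
#'
#' Frozen, file-backed term sets standing in for live ontology services.
#' Each vocabulary is a flat table of terms (CURIE-style identifier,
#' preferred label, synonyms, parents). The four vocabularies a MIxS-style
#' checklist needs are `environmental_package`, `biome`, `feature` and
#' `material`; bundled ENVO-style subsets live under
#' `system.file("extdata/vocab", package = "mixsheet")`. The bundled files
#' are small illustrative subsets, not authoritative ontology exports.
#'
#' Matching is case-insensitive on labels and synonyms and whitespace is
#' trimmed; identifiers match exactly. When a synonym collides with a label
#' (or with an earlier term's synonym) the label wins and the synonym is
#' ignored for lookup, deterministically.
#'
#' @name vocabularies
NULL

new_vocabulary <- function(name, terms) {
  ids <- vapply(terms, `[[`, "", "term_id")
  if (anyDuplicated(ids)) {
    abort_schema(sprintf("vocabulary '%s': duplicate term_id '%s'",
                         name, ids[duplicated(ids)][1]))
  }
  labels <- vapply(terms, `[[`, "", "label")
  folded <- tolower(labels)
  if (anyDuplicated(folded)) {
    dup <- folded[duplicated(folded)][1]
    clash <- ids[folded == dup]
    abort_schema(sprintf(
      "vocabulary '%s': terms %s share the label '%s' (case-folded)",
      name, paste(clash, collapse = " and "), dup))
  }
  for (t in terms) {
    bad <- setdiff(t$parents, ids)
    if (length(bad)) {
      abort_schema(sprintf("vocabulary '%s': term %s has dangling parent '%s'",
                           name, t$term_id, bad[1]))
    }
  }
  # Stable presentation order: by label, byte-wise.
  terms <- terms[radix_order(labels)]
  names(terms) <- vapply(terms, `[[`, "", "term_id")

  # Lookup map, labels first so label/synonym collisions resolve to labels.
  lut <- new.env(parent = emptyenv())
  for (t in terms) assign(tolower(t$label), t$term_id, envir = lut)
  for (t in terms) {
    for (s in t$synonyms) {
      k <- tolower(trim_ws(s))
      if (nzchar(k) && !exists(k, envir = lut, inherits = FALSE)) {
        assign(k, t$term_id, envir = lut)
      }
    }
  }
  structure(list(name = name, terms = terms, lut = lut),
            class = "controlled_vocabulary")
}

split_pipes <- function(x) {
  x <- x %||% ""
  if (is.na(x)) x <- ""
  x <- trim_ws(x)
  if (!nzchar(x)) return(character(0))
  trim_ws(strsplit(x, "|", fixed = TRUE)[[1]])
}

#' Load a controlled vocabulary from a term table
#'
#' The file is a UTF-8 TSV with a header row and columns `term_id`, `label`,
#' `synonyms` (pipe-separated) and `parents` (pipe-separated term_ids).
#'
#' @param path Path to the TSV file.
#' @param name Vocabulary name; defaults to the file name without extension.
#' @return A `controlled_vocabulary` object.
#' @examples
#' biome <- read_vocabulary(system.file("extdata/vocab/biome.tsv",
#'                                      package = "mixsheet"))
#' resolve_term(biome, "Marine Biome")$term_id
#' @export
read_vocabulary <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) abort_io(sprintf("vocabulary file '%s' does not exist", path))
  df <- tryCatch(
    utils::read.delim(path, colClasses = "character", sep = "\t", quote = "",
                      fileEncoding = "UTF-8", check.names = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse vocabulary '%s': %s",
                                            path, conditionMessage(e))))
  need <- c("term_id", "label")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("vocabulary '%s' must have columns term_id and label", path))
  }
  terms <- lapply(seq_len(nrow(df)), function(i) {
    list(term_id = trim_ws(df$term_id[i]), label = trim_ws(df$label[i]),
         synonyms = split_pipes(if ("synonyms" %in% names(df)) df$synonyms[i] else ""),
         parents = split_pipes(if ("parents" %in% names(df)) df$parents[i] else ""))
  })
  new_vocabulary(name, terms)
}

#' Write a controlled vocabulary to its TSV form
#'
#' @param vocab A `controlled_vocabulary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "controlled_vocabulary"))
  lines <- c("term_id\tlabel\tsynonyms\tparents",
             vapply(vocab$terms, function(t) {
               paste(t$term_id, t$label,
                     paste(t$synonyms, collapse = "|"),
                     paste(t$parents, collapse = "|"), sep = "\t")
             }, ""))
  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e) abort_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Import a vocabulary from an OBO file
#'
#' Convenience importer for `[Term]` stanzas of OBO-format ontology dumps:
#' reads `id`, `name`, `synonym` and `is_a` tags, skipping obsolete terms.
#' Parents outside the imported subset are dropped.
#'
#' @param path Path to an OBO file.
#' @param name Vocabulary name; defaults to the file name without extension.
#' @return A `controlled_vocabulary`.
#' @export
read_obo_vocabulary <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) abort_io(sprintf("OBO file '%s' does not exist", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && nzchar(cur$term_id %||% "")) {
      terms[[length(terms) + 1L]] <<- list(
        term_id = cur$term_id, label = cur$label %||% cur$term_id,
        synonyms = cur$synonyms %||% character(0),
        parents = cur$parents %||% character(0))
    }
    cur <<- NULL
  }
  for (ln in lines) {
    ln <- trim_ws(ln)
    if (ln == "[Term]") { flush(); in_term <- TRUE; cur <- list(); next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$term_id <- trim_ws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$label <- trim_ws(sub("^name:", "", ln))
    else if (grepl("^synonym:", ln)) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    } else if (grepl("^is_a:", ln)) {
      p <- trim_ws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, p)
    } else if (grepl("^is_obsolete: *true", ln)) cur$obsolete <- TRUE
  }
  flush()
  ids <- vapply(terms, `[[`, "", "term_id")
  terms <- lapply(terms, function(t) { t$parents <- intersect(t$parents, ids); t })
  new_vocabulary(name, terms)
}

#' Resolve a raw string to a vocabulary term
#'
#' Matches, in order: exact `term_id`; case-insensitive label;
#' case-insensitive synonym. Leading/trailing whitespace is ignored.
#'
#' @param vocab A `controlled_vocabulary`.
#' @param raw Raw string.
#' @return The matching term (a list with `term_id`, `label`, `synonyms`,
#'   `parents`) or `NULL` when the string resolves to no term.
#' @export
resolve_term <- function(vocab, raw) {
  stopifnot(inherits(vocab, "controlled_vocabulary"))
  raw <- trim_ws(as.character(raw))
  if (!nzchar(raw)) return(NULL)
  if (!is.null(vocab$terms[[raw]])) return(vocab$terms[[raw]])
  key <- tolower(raw)
  if (exists(key, envir = vocab$lut, inherits = FALSE)) {
    return(vocab$terms[[get(key, envir = vocab$lut)]])
  }
  NULL
}

#' Search a vocabulary
#'
#' Ranking: exact label match first, then label prefix, then label
#' substring, then synonym matches; within a rank, ties break
#' lexicographically by label. An empty query returns the first `limit`
#' terms in label order. Matching is case-insensitive on the trimmed query.
#'
#' @param vocab A `controlled_vocabulary`.
#' @param query Query string.
#' @param limit Maximum number of terms to return (>= 1).
#' @return List of terms, best first, at most `limit` long.
#' @export
search_terms <- function(vocab, query, limit = 10L) {
  stopifnot(inherits(vocab, "controlled_vocabulary"))
  limit <- as.integer(limit)
  if (is.na(limit) || limit < 1L) abort_argument("limit must be >= 1")
  q <- tolower(trim_ws(as.character(query)))
  terms <- vocab$terms   # already in label order
  if (!nzchar(q)) return(utils::head(unname(terms), limit))
  rank <- vapply(terms, function(t) {
    lab <- tolower(t$label)
    if (lab == q) return(1L)
    if (startsWith(lab, q)) return(2L)
    if (grepl(q, lab, fixed = TRUE)) return(3L)
    syn <- tolower(t$synonyms)
    if (length(syn) && any(grepl(q, syn, fixed = TRUE))) return(4L)
    NA_integer_
  }, 1L)
  hit <- which(!is.na(rank))
  hit <- hit[radix_order(rank[hit])]   # stable: label order within rank
  utils::head(unname(terms[hit]), limit)
}

#' Load every vocabulary in a directory
#'
#' Reads each `*.tsv` file as one vocabulary named after the file.
#'
#' @param dir Directory of vocabulary TSV files.
#' @return Named list of `controlled_vocabulary` objects.
#' @export
read_vocabulary_dir <- function(dir) {
  if (!dir.exists(dir)) abort_io(sprintf("vocabulary directory '%s' does not exist", dir))
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  vocabs <- lapply(files, read_vocabulary)
  names(vocabs) <- vapply(vocabs, `[[`, "", "name")
  vocabs
}

#' @export
print.controlled_vocabulary <- function(x, ...) {
  cat(sprintf("<controlled_vocabulary> %s: %d terms\n", x$name, length(x$terms)))
  invisible(x)
}
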