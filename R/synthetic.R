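#' Seeded bundle generation and exact error injection
#'
#' [make_valid_bundle()] builds a bundle that passes [validate_bundle()]
#' with zero errors: every declared field of every collection is filled
#' with a type-valid value, controlled-vocabulary fields draw uniformly
#' from the vocabulary, dates fall in a fixed 2010-2015 window and
#' coordinates stay in range. [inject_errors()] then corrupts a valid
#' bundle at seeded, randomly chosen eligible locations and returns a
#' ledger of exactly the defects applied — the ground-truth oracle against
#' which the validator's precision and recall are measured.
#'
#' The injector mutates after generation rather than generating invalid
#' data directly, so the ground truth is exact by construction. Two
#' cascade-prone defects are constrained to keep one-defect-one-issue
#' exact: `broken_link` is injected only at the library tier (breaking an
#' ep block's link would additionally orphan its sample), and `no_samples`
#' removes samples together with their children (so it is feasible alone
#' or alongside project-level defects only).
#'
#' @name synthetic
NULL

#' Issue codes the injector can produce
#' @return Character vector of injectable codes.
#' @export
injectable_codes <- function() {
  c("not_integer", "not_decimal", "not_iso_date", "not_iso_time",
    "not_iso_datetime", "out_of_range", "bad_url", "bad_email",
    "cv_violation", "pattern_mismatch", "missing_required", "unknown_key",
    "broken_link", "missing_ep", "no_samples")
}

code_types <- function(code) {
  switch(code,
    not_integer = "integer", not_decimal = "decimal",
    not_iso_date = "date", not_iso_time = "time",
    not_iso_datetime = "datetime", out_of_range = c("latitude", "longitude"),
    bad_url = "url", bad_email = "email", cv_violation = "cv_term",
    pattern_mismatch = "pattern", NULL)
}

random_words <- function(n = 2L) {
  pool <- c("coastal", "surface", "offshore", "benthic", "pelagic", "littoral",
            "estuarine", "upland", "riparian", "alpine", "boreal", "temperate")
  paste(sample(pool, n, replace = TRUE), collapse = " ")
}

random_value <- function(field, vocabs, package) {
  switch(field$type,
    text = random_words(),
    integer = as.character(sample.int(500L, 1L)),
    decimal = sprintf("%.2f", stats::runif(1, 0, 100)),
    date = format(as.Date("2010-01-01") + sample.int(2190L, 1L) - 1L, "%Y-%m-%d"),
    time = sprintf("%02d:%02d:%02d", sample(0:23, 1), sample(0:59, 1), sample(0:59, 1)),
    datetime = sprintf("%sT%02d:%02d:%02dZ",
                       format(as.Date("2010-01-01") + sample.int(2190L, 1L) - 1L, "%Y-%m-%d"),
                       sample(0:23, 1), sample(0:59, 1), sample(0:59, 1)),
    latitude = sprintf("%.4f", stats::runif(1, -90, 90)),
    longitude = sprintf("%.4f", stats::runif(1, -180, 180)),
    url = sprintf("https://example.org/projects/%d", sample.int(10000L, 1L)),
    email = sprintf("user%d@example.org", sample.int(10000L, 1L)),
    cv_term = {
      vocab <- vocabs[[field$vocab]]
      if (is.null(vocab)) abort_config(sprintf("vocabulary '%s' is not registered", field$vocab))
      if (field$key == "env_package" && !is.null(resolve_term(vocab, package))) {
        resolve_term(vocab, package)$label
      } else {
        labels <- vapply(vocab$terms, `[[`, "", "label")
        labels[[sample.int(length(labels), 1L)]]
      }
    },
    pattern = {
      if (!nzchar(field$example) || !check_gatekeeper(field$pattern, field$example)) {
        abort_config(sprintf(
          "field '%s': pattern fields need an example matching their gatekeeper for generation",
          field$key))
      }
      field$example
    },
    abort_config(sprintf("cannot generate a value for type '%s'", field$type)))
}

fill_fields <- function(cs, vocabs, package) {
  vals <- lapply(cs$fields, random_value, vocabs = vocabs, package = package)
  stats::setNames(vals, vapply(cs$fields, `[[`, "", "key"))
}

#' Generate a valid project bundle
#'
#' @param template A [metadata_template()].
#' @param vocabs Named list of vocabularies covering the template's
#'   cv_term references.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param n_samples Number of samples (>= 0).
#' @param n_libraries_per_sample Libraries per sample (>= 0).
#' @param package Environmental package subtype for all samples; defaults
#'   to the template's first ep collection.
#' @param library_subtype Library type; defaults to the template's first
#'   library collection.
#' @return A `project_bundle` for which [validate_bundle()] reports zero
#'   errors (zero issues when `n_samples > 0`).
#' @export
make_valid_bundle <- function(template, vocabs, seed = 1L, n_samples = 3L,
                              n_libraries_per_sample = 1L, package = NULL,
                              library_subtype = NULL) {
  stopifnot(inherits(template, "metadata_template"))
  n_samples <- as.integer(n_samples)
  n_lib <- as.integer(n_libraries_per_sample)
  if (n_samples < 0L || n_lib < 0L) abort_argument("counts must be >= 0")
  subtypes <- function(nm) {
    specs <- Filter(function(cs) cs$name == nm, template$collections)
    vapply(specs, `[[`, "", "subtype")
  }
  package <- package %||% subtypes("ep")[1]
  library_subtype <- library_subtype %||% subtypes("library")[1]
  if (!has_collection(template, collection_id("ep", package))) {
    abort_lookup(sprintf("template '%s' knows no environmental package '%s'",
                         template$name, package))
  }
  with_seed(seed, {
    b <- new_bundle(template, sprintf("project_%04d", sample.int(9999L, 1L)))
    b$project$values <- fill_fields(template_collection(template, "project"),
                                    vocabs, package)
    sample_cs <- template_collection(template, "sample")
    ep_cs <- template_collection(template, collection_id("ep", package))
    lib_cs <- template_collection(template, collection_id("library", library_subtype))
    for (i in seq_len(n_samples)) {
      sid <- sprintf("sample_%02d", i)
      b <- add_sample(b, sid, fill_fields(sample_cs, vocabs, package), package,
                      fill_fields(ep_cs, vocabs, package))
      for (j in seq_len(n_lib)) {
        b <- add_library(b, sid, sprintf("lib_%02d_%d", i, j), library_subtype,
                         fill_fields(lib_cs, vocabs, package))
      }
    }
    b
  })
}

bad_value_for <- function(code, field) {
  switch(code,
    not_integer = "3.5",
    not_decimal = "four point two",
    not_iso_date = sample(c("12/31/2013", "2013-2-9", "2013-02-30", "20130209"), 1),
    not_iso_time = sample(c("25:10", "9:05", "10:61", "10h30"), 1),
    not_iso_datetime = sample(c("2013-02-09 10:30:00", "2013-02-09T25:00", "someday"), 1),
    out_of_range = if (field$type == "latitude") {
      sample(c("91.5", "-95.0"), 1)
    } else sample(c("200.1", "-181.0"), 1),
    bad_url = "not a url at all",
    bad_email = "nobody-at-example.org",
    cv_violation = "not_a_real_term_zzz",
    pattern_mismatch = "??mismatch??",
    abort_argument(sprintf("no bad value for code '%s'", code)))
}

#' Eligible injection locations for one issue code
#'
#' @param bundle A `project_bundle` (normally valid).
#' @param template The template in force.
#' @param code One of [injectable_codes()].
#' @return Data frame with columns `entity`, `collection`, `key`: the
#'   locations where injecting `code` would produce exactly that issue.
#' @export
eligible_locations <- function(bundle, template, code) {
  loc <- function(entity = character(0), collection = character(0), key = character(0)) {
    data.frame(entity = entity, collection = collection, key = key,
               stringsAsFactors = FALSE)
  }
  if (code == "no_samples") {
    if (length(bundle$samples) == 0L) return(loc())
    return(loc(bundle$project$id, "project", ""))
  }
  if (code == "missing_ep") {
    eps <- vapply(bundle$eps, function(e) (e$values[["sample_name"]] %||% "")[1], "")
    sids <- intersect(names(bundle$samples), eps)
    return(loc(sids, rep("sample", length(sids)), rep("", length(sids))))
  }
  if (code == "broken_link") {
    ids <- names(bundle$libraries)
    cols <- vapply(bundle$libraries, `[[`, "", "collection")
    return(loc(ids, unname(cols), rep("sample_name", length(ids))))
  }
  if (!code %in% c("unknown_key", "missing_required") &&
      is.null(code_types(code))) {
    abort_argument(sprintf("unknown issue code '%s'", code))
  }
  ids <- character(0); cols <- character(0); keys <- character(0)
  for (e in bundle_entities(bundle)) {
    if (!has_collection(template, e$collection)) next
    cs <- template_collection(template, e$collection)
    ks <- if (code == "unknown_key") {
      NA_character_
    } else if (code == "missing_required") {
      rk <- required_fields(template, e$collection)
      rk[vapply(rk, function(k) {
        v <- e$values[[k]]
        !is.null(v) && any(nzchar(trim_ws(v)))
      }, TRUE)]
    } else {
      types <- code_types(code)
      fk <- vapply(cs$fields, `[[`, "", "key")
      fk[vapply(cs$fields, `[[`, "", "type") %in% types]
    }
    if (length(ks)) {
      ids <- c(ids, rep(e$id, length(ks)))
      cols <- c(cols, rep(e$collection, length(ks)))
      keys <- c(keys, ks)
    }
  }
  loc(ids, cols, keys)
}

#' Inject a requested mix of defects into a valid bundle
#'
#' Applies exactly the requested defects at seeded random eligible
#' locations and returns the corrupted bundle together with the ledger of
#' `(location, code)` pairs — on a previously valid bundle,
#' [validate_bundle()] must report exactly the ledger.
#'
#' @param bundle A valid `project_bundle`.
#' @param error_mix Named integer vector/list: issue code -> count.
#' @param seed Integer seed.
#' @param template Template in force; defaults to `bundle$template`.
#' @return List with `bundle` (corrupted) and `ledger` (data frame
#'   `entity`, `collection`, `key`, `code`).
#' @export
inject_errors <- function(bundle, error_mix, seed = 1L, template = bundle$template) {
  stopifnot(inherits(bundle, "project_bundle"))
  counts <- unlist(error_mix)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort_argument("error_mix must be a named code -> count mapping")
  }
  bad <- setdiff(names(counts), injectable_codes())
  if (length(bad)) abort_argument(sprintf("unknown issue code '%s'", bad[1]))
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_argument("counts must be non-negative integers")
  }
  order_ <- intersect(c("no_samples", "missing_ep", "broken_link",
                        setdiff(injectable_codes(),
                                c("no_samples", "missing_ep", "broken_link",
                                  "missing_required", "unknown_key")),
                        "missing_required", "unknown_key"),
                      names(counts)[counts > 0])
  ledger <- data.frame(entity = character(0), collection = character(0),
                       key = character(0), code = character(0),
                       stringsAsFactors = FALSE)
  with_seed(seed, {
    used <- character(0)
    unknown_n <- 0L
    for (code in order_) {
      for (rep_ in seq_len(counts[[code]])) {
        el <- eligible_locations(bundle, template, code)
        if (nrow(el)) {
          tag <- paste0(el$entity, "\r", el$key)
          el <- el[!tag %in% used, , drop = FALSE]
        }
        if (!nrow(el)) {
          abort_argument(sprintf(
            "error mix is infeasible: no eligible location left for '%s'", code))
        }
        pick <- el[sample.int(nrow(el), 1L), ]
        used <- c(used, paste0(pick$entity, "\r", pick$key))
        if (code == "no_samples") {
          for (id in c(names(bundle$samples), names(bundle$libraries),
                       names(bundle$eps))) {
            bundle <- drop_entity(bundle, id)
            used <- c(used, paste0(id, "\r"))
          }
        } else if (code == "missing_ep") {
          epid <- names(bundle$eps)[vapply(bundle$eps, function(e)
            (e$values[["sample_name"]] %||% "")[1] == pick$entity, TRUE)][1]
          bundle <- drop_entity(bundle, epid)
          used <- c(used, paste0(epid, "\r"))
        } else if (code == "broken_link") {
          bundle <- set_value(bundle, pick$entity, "sample_name", "no_such_sample_zzz")
        } else if (code == "missing_required") {
          bundle <- set_value(bundle, pick$entity, pick$key, "")
        } else if (code == "unknown_key") {
          unknown_n <- unknown_n + 1L
          pick$key <- sprintf("custom_note_%d", unknown_n)
          bundle <- set_value(bundle, pick$entity, pick$key, random_words())
          used <- c(used, paste0(pick$entity, "\r", pick$key))
        } else {
          cs <- template_collection(template, pick$collection)
          f <- cs$fields[[match(pick$key, vapply(cs$fields, `[[`, "", "key"))]]
          bundle <- set_value(bundle, pick$entity, pick$key, bad_value_for(code, f))
        }
        ledger <- rbind(ledger, data.frame(
          entity = pick$entity, collection = pick$collection, key = pick$key,
          code = code, stringsAsFactors = FALSE))
      }
    }
  })
  ledger <- ledger[radix_order(ledger$collection, ledger$entity,
                               ledger$key, ledger$code), , drop = FALSE]
  rownames(ledger) <- NULL
  list(bundle = bundle, ledger = ledger)
}

#' Write an injection ledger as TSV
#'
#' @param ledger Ledger data frame from [inject_errors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e) abort_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeLines(c("entity\tcollection\tkey\tcode",
               if (nrow(ledger)) paste(ledger$entity, ledger$collection,
                                       ledger$key, ledger$code, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
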