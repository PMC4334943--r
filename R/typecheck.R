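#' Level-1 validation: values against data types
#'
#' The first validation level checks that each raw value constrains to its
#' field's declared data type: integers and decimals must parse as such,
#' dates and times must be ISO 8601 (extended format only: `YYYY-MM-DD`,
#' `HH:MM[:SS]`, `date'T'time` with an optional `Z`/`+HH:MM` zone),
#' coordinates must be decimal degrees within range, and regex gatekeepers
#' must match the full string. Leading/trailing whitespace is trimmed
#' before every check; internal whitespace is significant.
#'
#' Empty strings raise no level-1 issue: a blank required field is a
#' structural (level-2) problem, which keeps the two levels disjoint.
#'
#' @name typecheck
NULL

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  if (month == 2L && leap) 29L else dm[month]
}

parse_iso_date <- function(raw) {
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", raw)) return(NULL)
  y <- as.integer(substr(raw, 1, 4))
  m <- as.integer(substr(raw, 6, 7))
  d <- as.integer(substr(raw, 9, 10))
  if (m < 1L || m > 12L) return(NULL)
  if (d < 1L || d > days_in_month(y, m)) return(NULL)
  list(year = y, month = m, day = d, iso = raw)
}

parse_iso_time <- function(raw) {
  if (!grepl("^[0-9]{2}:[0-9]{2}(:[0-9]{2})?$", raw)) return(NULL)
  h <- as.integer(substr(raw, 1, 2))
  mi <- as.integer(substr(raw, 4, 5))
  s <- if (nchar(raw) == 8L) as.integer(substr(raw, 7, 8)) else 0L
  if (h > 23L || mi > 59L || s > 59L) return(NULL)
  list(hour = h, minute = mi, second = s, iso = raw)
}

parse_iso_datetime <- function(raw) {
  if (!grepl("T", raw, fixed = TRUE)) return(NULL)
  parts <- strsplit(raw, "T", fixed = TRUE)[[1]]
  if (length(parts) != 2L) return(NULL)
  d <- parse_iso_date(parts[1])
  if (is.null(d)) return(NULL)
  timepart <- parts[2]
  zone <- ""
  zm <- regexpr("(Z|[+-][0-9]{2}:[0-9]{2})$", timepart)
  if (zm > 0L) {
    zone <- substr(timepart, zm, nchar(timepart))
    timepart <- substr(timepart, 1L, zm - 1L)
    if (zone != "Z") {
      zh <- as.integer(substr(zone, 2, 3)); zmin <- as.integer(substr(zone, 5, 6))
      if (zh > 14L || zmin > 59L) return(NULL)
    }
  }
  t <- parse_iso_time(timepart)
  if (is.null(t)) return(NULL)
  list(date = d, time = t, zone = zone, iso = raw)
}

re_integer <- "^[+-]?[0-9]+$"
re_decimal <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

parse_decimal <- function(raw) {
  if (!grepl(re_decimal, raw)) return(NULL)
  as.numeric(raw)
}

#' Full-string regex gatekeeper
#'
#' Syntax gatekeepers are implicitly anchored: the whole value must match
#' the pattern, not merely contain a match.
#'
#' @param pattern Regex source (must compile; checked at template load).
#' @param raw Raw string (not trimmed; callers trim).
#' @return `TRUE` iff the full string matches.
#' @export
check_gatekeeper <- function(pattern, raw) {
  grepl(paste0("^(?:", pattern, ")$"), raw, perl = TRUE)
}

type_issue <- function(code, field, raw, detail) {
  list(code = code,
       message = sprintf("value '%s' for field '%s': %s", raw, field$key, detail))
}

#' Validate one raw value against a field definition
#'
#' The level-1 check. Returns the typed value together with the (possibly
#' empty) list of issues; a typed value is present exactly when no issue
#' was raised. An empty (or all-whitespace) raw string yields neither a
#' value nor an issue: required-field enforcement is level 2's job.
#'
#' @param field A [field_definition()].
#' @param raw Raw string value.
#' @param vocabs Named list of `controlled_vocabulary` objects; must contain
#'   `field$vocab` when the field is a `cv_term` (otherwise a configuration
#'   error is signalled, distinct from a validation issue).
#' @return List with elements `value` (the parsed representation, or `NULL`)
#'   and `issues` (list of `code`/`message` pairs).
#' @examples
#' f <- field_definition("collection_date", type = "date")
#' validate_value(f, "2014-12-08")$value$iso
#' validate_value(f, "12/08/2014")$issues[[1]]$code
#' @export
validate_value <- function(field, raw, vocabs = list()) {
  raw <- trim_ws(as.character(raw))
  if (!nzchar(raw)) return(list(value = NULL, issues = list()))
  iss <- list()
  val <- NULL
  switch(field$type,
    text = { val <- raw },
    integer = {
      if (grepl(re_integer, raw)) val <- raw
      else iss <- list(type_issue("not_integer", field, raw,
                                  "not an integer (optional sign + digits)"))
    },
    decimal = {
      v <- parse_decimal(raw)
      if (!is.null(v)) val <- v
      else iss <- list(type_issue("not_decimal", field, raw, "not a decimal number"))
    },
    date = {
      v <- parse_iso_date(raw)
      if (!is.null(v)) val <- v
      else iss <- list(type_issue("not_iso_date", field, raw,
                                  "not an ISO 8601 calendar date (YYYY-MM-DD)"))
    },
    time = {
      v <- parse_iso_time(raw)
      if (!is.null(v)) val <- v
      else iss <- list(type_issue("not_iso_time", field, raw,
                                  "not an ISO 8601 time (HH:MM or HH:MM:SS, 24-hour)"))
    },
    datetime = {
      v <- parse_iso_datetime(raw)
      if (!is.null(v)) val <- v
      else iss <- list(type_issue("not_iso_datetime", field, raw,
                                  "not an ISO 8601 datetime (date'T'time, optional zone)"))
    },
    latitude = {
      v <- parse_decimal(raw)
      if (is.null(v)) iss <- list(type_issue("not_decimal", field, raw,
                                             "latitude must be decimal degrees"))
      else if (v < -90 || v > 90) iss <- list(type_issue("out_of_range", field, raw,
                                                         "latitude outside [-90, 90]"))
      else val <- v
    },
    longitude = {
      v <- parse_decimal(raw)
      if (is.null(v)) iss <- list(type_issue("not_decimal", field, raw,
                                             "longitude must be decimal degrees"))
      else if (v < -180 || v > 180) iss <- list(type_issue("out_of_range", field, raw,
                                                           "longitude outside [-180, 180]"))
      else val <- v
    },
    url = {
      if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://[^ \t]+$", raw)) val <- raw
      else iss <- list(type_issue("bad_url", field, raw, "not a URL (scheme://authority)"))
    },
    email = {
      if (grepl("^[^@ \t]+@[^@ \t]+\\.[^@ \t.]+$", raw)) val <- raw
      else iss <- list(type_issue("bad_email", field, raw, "not an email address"))
    },
    cv_term = {
      vocab <- vocabs[[field$vocab]]
      if (is.null(vocab)) {
        abort_config(sprintf("vocabulary '%s' (field '%s') is not registered",
                             field$vocab, field$key))
      }
      t <- resolve_term(vocab, raw)
      if (!is.null(t)) val <- t
      else iss <- list(type_issue("cv_violation", field, raw,
                                  sprintf("not a term of vocabulary '%s'", field$vocab)))
    },
    pattern = {
      if (check_gatekeeper(field$pattern, raw)) val <- raw
      else iss <- list(type_issue("pattern_mismatch", field, raw,
                                  sprintf("does not match gatekeeper '%s'", field$pattern)))
    },
    abort_config(sprintf("unhandled data type tag '%s'", field$type))
  )
  list(value = val, issues = iss)
}
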