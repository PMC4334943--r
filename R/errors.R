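# Classed conditions used across the package. The CLI maps these onto exit
# codes, so every user-facing failure goes through mx_abort().

mx_abort <- function(class, msg, ...) {
  cnd <- structure(
    class = c(class, "mixsheet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

abort_parse    <- function(msg, ...) mx_abort("mixsheet_parse_error", msg, ...)
abort_schema   <- function(msg, ...) mx_abort("mixsheet_schema_error", msg, ...)
abort_lookup   <- function(msg, ...) mx_abort("mixsheet_lookup_error", msg, ...)
abort_conflict <- function(msg, ...) mx_abort("mixsheet_conflict_error", msg, ...)
abort_argument <- function(msg, ...) mx_abort("mixsheet_argument_error", msg, ...)
abort_config   <- function(msg, ...) mx_abort("mixsheet_config_error", msg, ...)
abort_io       <- function(msg, ...) mx_abort("mixsheet_io_error", msg, ...)
abort_reference <- function(msg, ...) mx_abort("mixsheet_reference_error", msg, ...)

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

trim_ws <- function(x) gsub("^[ \t\r\n]+|[ \t\r\n]+$", "", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable lexicographic (byte-wise) ordering, independent of the locale.
radix_order <- function(...) order(..., method = "radix")
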