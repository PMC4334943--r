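#' Seeded soundness/completeness trials for the validator
#'
#' Runs repeated generate -> corrupt -> validate trials and scores the
#' validator against the injection ledger on exact `(entity, collection,
#' key, code)` agreement. Each trial draws a bundle of 1-10 samples with
#' 0-4 libraries each and a feasible mix of 1-6 defects across all
#' injectable codes (a dedicated slice of trials exercises the
#' `no_samples` defect alone, since it removes every location the other
#' codes would need). Defect mixes are drawn by rejection: a candidate mix
#' that requests more defects than the bundle has eligible locations for
#' is redrawn, which enforces the injector's feasibility precondition
#' without biasing where defects land.
#'
#' @param template A [metadata_template()].
#' @param vocabs Vocabularies for the template.
#' @param n_trials Number of trials.
#' @param seed Base seed; trial t uses seed `seed * 10000 + t` internally.
#' @return List with fields `n_trials`, `n_defects`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `n_exact_trials` (trials where report and
#'   ledger agreed exactly), `levels_disjoint` and `levels_additive`
#'   (logical: held in every trial).
#' @export
run_validation_trials <- function(template, vocabs, n_trials = 500L, seed = 1L) {
  tp <- fp <- fn <- 0L
  n_defects <- 0L
  n_exact <- 0L
  disjoint <- additive <- TRUE
  key_of <- function(df) paste(df$entity, df$collection, df$key, df$code, sep = "\r")
  for (t in seq_len(n_trials)) {
    seed_t <- seed * 10000L + t
    dims <- with_seed(seed_t, c(sample(1:10, 1), sample(0:4, 1)))
    b <- make_valid_bundle(template, vocabs, seed = seed_t,
                           n_samples = dims[1], n_libraries_per_sample = dims[2])
    if (t %% 25L == 0L) {
      inj <- inject_errors(b, list(no_samples = 1L), seed = seed_t)
    } else {
      pool <- setdiff(injectable_codes(), "no_samples")
      if (dims[2] == 0L) pool <- setdiff(pool, "broken_link")
      caps <- vapply(pool, function(code)
        nrow(eligible_locations(b, template, code)), 1L)
      inj <- NULL
      for (attempt in 1:25) {
        mix <- with_seed(seed_t + 1000000L * attempt, {
          n_def <- sample(1:6, 1)
          counts <- stats::setNames(integer(length(pool)), pool)
          for (d in seq_len(n_def)) {
            open <- pool[counts < caps[pool]]
            if (!length(open)) break
            pick <- if (length(open) == 1L) open else sample(open, 1)
            counts[[pick]] <- counts[[pick]] + 1L
          }
          as.list(counts[counts > 0])
        })
        inj <- tryCatch(inject_errors(b, mix, seed = seed_t + attempt),
                        mixsheet_argument_error = function(e) NULL)
        if (!is.null(inj)) break
      }
      if (is.null(inj)) next  # no feasible mix found; trial skipped
    }
    v1 <- validate_values(inj$bundle, template, vocabs)
    v2 <- validate_structure(inj$bundle, template)
    vb <- validate_bundle(inj$bundle, template, vocabs)
    got <- key_of(vb); want <- key_of(inj$ledger)
    tp <- tp + length(intersect(got, want))
    fp <- fp + length(setdiff(got, want))
    fn <- fn + length(setdiff(want, got))
    n_defects <- n_defects + nrow(inj$ledger)
    if (setequal(got, want) && length(got) == length(want)) n_exact <- n_exact + 1L
    if (length(intersect(v1$code, v2$code)) > 0) disjoint <- FALSE
    if (nrow(vb) != nrow(v1) + nrow(v2) ||
        !setequal(key_of(vb), c(key_of(v1), key_of(v2)))) additive <- FALSE
  }
  list(n_trials = n_trials, n_defects = n_defects, tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       n_exact_trials = n_exact,
       levels_disjoint = disjoint, levels_additive = additive)
}
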