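# Shared fixtures: the bundled example template and vocabularies, a tiny
# hand-built template, and a brute-force search oracle.

fx_template_path <- function() {
  system.file("extdata/templates/mixs_core.yaml", package = "mixsheet")
}

fx_vocab_dir <- function() {
  system.file("extdata/vocab", package = "mixsheet")
}

fx_template <- function() read_template(fx_template_path())

fx_vocabs <- function() read_vocabulary_dir(fx_vocab_dir())

# Minimal but complete template built in code (no file involved).
tiny_template <- function(vocabularies = c("biome")) {
  metadata_template(
    name = "tiny", version = "0.1",
    collections = list(
      collection_spec("project", fields = list(
        field_definition("pi_organization", label = "PI Organization",
                         required = TRUE),
        field_definition("project_url", type = "url"))),
      collection_spec("sample", fields = list(
        field_definition("collection_date", type = "date", required = TRUE),
        field_definition("latitude", type = "latitude", required = TRUE),
        field_definition("biome", type = "cv_term", vocab = "biome",
                         required = TRUE))),
      collection_spec("library", "metagenome", fields = list(
        field_definition("seq_meth", required = TRUE))),
      collection_spec("ep", "water", fields = list(
        field_definition("water_temperature", type = "decimal")))),
    vocabularies = vocabularies)
}

# Independent re-implementation of the documented search ranking, used as
# the oracle search_terms() is compared against.
brute_force_search <- function(vocab, query, limit) {
  q <- tolower(gsub("^\\s+|\\s+$", "", query))
  terms <- vocab$terms
  labels <- vapply(terms, `[[`, "", "label")
  terms <- terms[order(labels, method = "radix")]
  labels <- sort(labels, method = "radix")
  if (!nzchar(q)) return(unname(head(terms, limit)))
  score <- function(t) {
    lab <- tolower(t$label)
    if (lab == q) 1
    else if (substr(lab, 1, nchar(q)) == q) 2
    else if (grepl(q, lab, fixed = TRUE)) 3
    else if (any(grepl(q, tolower(t$synonyms), fixed = TRUE))) 4
    else Inf
  }
  s <- vapply(terms, score, 1)
  keep <- is.finite(s)
  unname(head(terms[keep][order(s[keep], method = "radix")], limit))
}

# (entity, collection, key, code) set from a report or ledger, for exact
# oracle comparison.
issue_set <- function(df) {
  sort(paste(df$entity, df$collection, df$key, df$code, sep = "\r"))
}
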