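# mixsheet

Checklist-driven capture and validation of metagenomic project metadata,
offline and scriptable.

## The problem

Sequence data without contextual metadata — where a sample came from, when,
from what material, under which protocol — loses most of its reuse value,
and most submitters record metadata late, inconsistently, or not at all.
The Genomic Standards Consortium's MIxS checklists define the minimum
information a metagenomic sample should carry: a core checklist per data
type combined with a pluggable *environmental package* (water, soil, air,
...) describing the sampled environment, with key fields constrained to
controlled vocabularies (ENVO-style biome / feature / material terms).

`mixsheet` is an R toolkit for that capture-and-validate loop, aimed at
people who curate or submit metagenomic sample metadata and at pipeline
authors who need machine-checkable metadata before sequences move on:

* **Standards as data.** Checklists and environmental packages live in
  plain YAML files (`inst/docs/template-format.md`); swapping or extending
  a standard is a file edit, never a code change
  (`read_template()`, `attach_package()`, `required_fields()`).
* **EAV storage.** All metadata are `id | collection | key | value`
  records: arbitrary key-value pairs first, per-collection contracts
  second (`kv_put()`, `kv_entities()`, four-column TSV dump).
* **Three-tier bundles.** One project, many samples, many libraries
  ("extractions") per sample, exactly one environmental-package block per
  sample (`new_bundle()`, `add_sample()`, `add_library()`,
  `prefill_project()` for reusing stored project-level metadata).
* **Two-level validation.** Level 1 checks each value against its
  declared data type (ISO 8601 dates/times, integer/decimal, WGS84
  decimal-degree coordinates, URL/email shape, full-string regex
  gatekeepers, controlled-vocabulary membership). Level 2 checks the
  structure against the template (required fields, unknown keys as
  warnings, hierarchy integrity). The levels are disjoint by construction
  and merge into one located, deterministic report (`validate_bundle()`).
* **Spreadsheet round trip.** Multi-sheet workbooks — one sheet per
  collection, canonical keys in row 1, annotated labels in row 2 — written
  and read in XLSX or a diffable TSV-per-sheet dialect
  (`blank_workbook()`, `write_workbook()`, `read_workbook()`).
* **Exact test oracle.** A seeded generator produces valid bundles; a
  corruption injector applies a requested defect mix and returns the
  ledger of exactly what it broke, against which the validator's precision
  and recall are scored (`make_valid_bundle()`, `inject_errors()`,
  `run_validation_trials()`).

## Worked example

```r
library(mixsheet)

tpl    <- read_template(system.file("extdata/templates/mixs_core.yaml",
                                    package = "mixsheet"))
vocabs <- read_vocabulary_dir(system.file("extdata/vocab", package = "mixsheet"))
tpl
#> <metadata_template> mixs-core-example (version 1.0)
#>   project                  6 fields (4 required)
#>   sample                   13 fields (7 required)
#>   library metagenome       4 fields (1 required)
#>   ep water                 4 fields (1 required)
#>   ep soil                  4 fields (1 required)
#>   vocabularies: environmental_package, biome, feature, material

b <- make_valid_bundle(tpl, vocabs, seed = 42, n_samples = 2,
                       n_libraries_per_sample = 2)
b
#> <project_bundle> project 'project_2369': 2 samples, 4 libraries, 2 ep blocks
validate_bundle(b, tpl, vocabs)
#> <validation_report> VALID: 0 error(s), 0 warning(s)

b2 <- set_value(b,  "sample_01", "collection_date", "12/31/2014")
b2 <- set_value(b2, b2$project$id, "pi_organization", "")
validate_bundle(b2, tpl, vocabs)
#> <validation_report> INVALID: 2 error(s), 0 warning(s)
#>   [error] missing_required   project/project_2369/pi_organization: required field 'pi_organization' is absent or blank
#>   [error] not_iso_date       sample/sample_01/collection_date: value '12/31/2014' for field 'collection_date': not an ISO 8601 calendar date (YYYY-MM-DD)
```

The first error is the classic web-form scenario — a required
PI-organization field left blank; the second is a level-1 data-type
violation. Reports are ordered deterministically (collection, entity, key,
code) and serialize to TSV via `format_report()`.

Vocabulary search ranks exact label matches first, then label prefixes,
substrings, and synonyms:

```r
for (t in search_terms(vocabs$biome, "mar", 3)) cat(t$term_id, t$label, "\n")
#> ENVO:01000049 marine benthic biome
#> ENVO:00000447 marine biome
#> ENVO:01000023 marine pelagic biome
```

A command-line wrapper covers the same loop
(`system.file("cli/mixsheet", package = "mixsheet")`):

```sh
mixsheet new      --template tpl.yaml --out metadata.xlsx
mixsheet validate metadata.xlsx --template tpl.yaml --vocab-dir vocab/
mixsheet generate --template tpl.yaml --vocab-dir vocab/ --out wb.xlsx \
                  --seed 3 --samples 4 --corrupt missing_required=2
mixsheet vocab-search biome "marine" --vocab-dir vocab/
```

Exit codes: 0 valid/success, 1 validation errors, 2 usage/configuration
error, 3 I/O or parse failure.

## Bundled data

`inst/extdata/templates/` holds the example core checklist and a pluggable
air package; `inst/extdata/vocab/` holds four small ENVO-style vocabulary
subsets (biome, feature, material, environmental package). These are
illustrative fixtures in ENVO CURIE style, not authoritative ontology or
MIxS exports. See `vignettes/metadata-validation.Rmd` for the methods
behind the validator and generator.
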