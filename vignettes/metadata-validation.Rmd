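---
title: "Two-level validation of checklist metadata: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level validation of checklist metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixsheet)
```

## The capture model

`mixsheet` models metagenomic project metadata the way submission
pipelines actually encounter it: as a flat table of
`id | collection | key | value` records. Anything can be recorded against
any entity — the entity-attribute-value layer imposes no schema — and
*collections* (project, sample, library, environmental package) overlay
per-collection contracts on top: which keys are required, what data type
each value must constrain to, and which values must come from a
controlled vocabulary. This hybrid is deliberate. Metadata capture fails
in practice when tools reject anything nonstandard, and it fails science
when tools accept everything silently; storing arbitrary pairs while
flagging departures from the checklist keeps both failure modes visible.

Studies are *bundles* with three tiers: one project, its samples, and the
sequencing libraries ("extractions") made from each sample, plus exactly
one environmental-package block per sample. Children point to their
sample through the reserved `sample_name` key, exactly as a flat
spreadsheet row would. Constructive operations (`add_sample()`,
`add_library()`) cannot create dangling references; bundles read back
from hand-edited workbooks can, and that is what the validator reports.

## The two validation levels

**Level 1 — values against data types** (`validate_values()`). Each raw
string whose key the template defines is checked against the field's
declared tag. The rules are strict and locale-free:

* `integer`: optional sign and digits only; `decimal`: standard decimal
  or scientific notation, dot decimal separator (comma decimals are
  rejected — a spreadsheet in a different locale should fail loudly, not
  silently reinterpret).
* `date` / `time` / `datetime`: ISO 8601 **extended** format only
  (`YYYY-MM-DD`, `HH:MM[:SS]` 24-hour, `date'T'time` with optional `Z` or
  `±HH:MM` offset), with real calendar validity computed from month
  lengths and the Gregorian leap rule. The basic format (`YYYYMMDD`) is
  rejected: one canonical profile keeps spreadsheets unambiguous, and
  eight undashed digits in a cell are more often a mangled number than a
  date. Datetimes without a zone designator are accepted and the offset
  is preserved when present — field scientists rarely record offsets, and
  rejecting zoneless timestamps would push users back to free text.
* `latitude` / `longitude`: decimal degrees (WGS84 assumed), range-checked
  to ±90/±180. Degree-minute-second strings are rejected: one machine
  form, convertible upstream.
* `url` / `email`: minimal shape checks (`scheme://authority`,
  `local@domain`); these are contact fields, not network probes.
* `cv_term`: the value must resolve in the referenced vocabulary;
  `pattern`: the **full** string must match the gatekeeper regex
  (implicit anchoring — "controlled syntax" means the whole value, so
  `AB12345` fails a `[A-Z]{2}[0-9]{4}` gatekeeper).

Leading/trailing whitespace is trimmed before every check; internal
whitespace is significant. An empty string raises no level-1 issue.

**Level 2 — structure against the template**
(`validate_structure()`). Required keys absent *or blank* raise
`missing_required` (a blank cell in a form is missing, whatever its
type); keys outside the checklist raise `unknown_key` as a **warning**,
never an error — the capture model promises that extra fields are kept
and flagged, not rejected. Hierarchy checks raise `no_samples`,
`missing_ep`, `broken_link`, and `unknown_collection` (an entity whose
collection the template in force does not define, which is how a
package-swapped template rejects data captured under another package).

The two levels are disjoint by construction: no code can be emitted by
both, blank-required enforcement lives only at level 2, and
`validate_bundle()` is their deterministic merge, ordered by (collection,
entity, key, code). A report is valid exactly when it contains no
error-severity issue. Severity is assigned per code in one table
(`inst/docs/template-format.md`); only `unknown_key` and `unknown_sheet`
are warnings.

## Templates and vocabularies as data

Templates are YAML documents; packages can live in separate files and be
attached (`attach_package()`) or removed without touching code.
Canonical keys are lowercase/underscore tokens while display labels keep
their original casing ("PI Organization" vs `pi_organization`), so
machine keys never drift with label cosmetics.

Vocabularies are frozen TSV term tables (identifier, preferred label,
pipe-separated synonyms and parents) standing in for live ontology
services; the lookup interface (`resolve_term()`, `search_terms()`) is
deliberately narrow so a live adapter could replace the files without
touching callers. Matching is case-insensitive on labels and synonyms
with whitespace trimmed (dropdowns match at label level), identifiers
match exactly, and label/synonym collisions resolve toward the label,
deterministically. Search ranks exact label, label prefix, label
substring, then synonym matches, with lexicographic tie-breaks. The
bundled biome/feature/material subsets use ENVO-style CURIEs and the
package list mirrors common MIxS package names, but they are illustrative
fixtures: which exact subsets backed the original production tool is not
recoverable, and nothing in the code depends on these particular terms.
An OBO importer (`read_obo_vocabulary()`) covers the common interchange
format.

## Workbooks

One sheet per collection; row 1 canonical keys, row 2 labels with units
and a `*` marking required fields, one entity per row from row 3. All
cells are read as text — no spreadsheet-native date or number coercion
ever touches a value before level-1 validation, which closes the
best-known spreadsheet corruption channel. Two dialects: XLSX for users,
and a TSV-per-sheet directory for tests and diffs, byte-deterministic
given a template (the XLSX container is also written with a constant
timestamp; bit-exactness is asserted only on the TSV dialect). The XLSX
writer is a minimal Office Open XML implementation (inline strings,
store-method ZIP) because workbooks here are plain text tables; reading
goes through `readxl`, so every xlsx round-trip test also cross-checks
the writer against an independent reader. Parse problems (unknown sheet,
duplicate header, blank or duplicate row identifier — first row wins) are
recorded as located issues, never exceptions, so a user sees one merged
report. One representational limit is documented rather than papered
over: a blank cell reads as "key absent", so an explicit empty-string
value survives the kvstore TSV dump but not a workbook round trip.

## The synthetic generator and the injection oracle

`make_valid_bundle()` fills **every** declared field of every collection
with a type-valid value: CV fields draw uniformly from their vocabulary,
dates from a fixed 2010–2015 window, coordinates uniformly in range,
pattern fields use the field's declared example. Generation is
deterministic per seed, with the caller's RNG state restored afterwards.
The generator emulates *structurally and typically valid* submissions;
it does not emulate realistic biological value distributions,
correlations between fields, or the messiness of free text. Passing
round-trip and oracle tests therefore demonstrates the machinery is
sound, not that real-world metadata will be clean — real workbooks are
expected to fail validation, which is the point of the tool.

`inject_errors()` corrupts *after* generation so the ground truth is
exact: it returns a ledger of precisely the `(location, code)` defects
applied, and on a previously valid bundle the validator must report
exactly the ledger. Two defect classes cascade and are constrained to
keep one defect ↔ one issue: `broken_link` is injected only at the
library tier (orphaning an ep block would also strand its sample), and
`no_samples` removes samples together with their children, so it is
exercised in dedicated single-defect trials. `run_validation_trials()`
scores precision and recall over seeded trials (bundles of 1–10 samples,
0–4 libraries each, 1–6 defects); candidate defect mixes that exceed a
bundle's eligible locations are redrawn, enforcing the injector's
feasibility precondition without biasing placements.

## Numerical and procedural choices

* Problem sizes in the shipped tests and acceptance script — 500
  corruption trials, 100 round-trip bundles, a ~9.5×10³-string date
  grammar, 50 search queries — are the package's chosen verification
  scale: large enough that every issue code, both dialects, and the
  calendar edge cases (leap years, month lengths, century rule) are
  exercised many times over.
* The date oracle in the tests is base R's calendar (`as.Date` with an
  explicit format) plus the documented shape regex; the implementation
  does its own month-length arithmetic, keeping the two routes
  independent.
* Duplicate workbook rows: first wins, error recorded — deterministic and
  lossless in the report.
* Single-valued fields are the default (spreadsheet cells are
  single-valued); multi-valued fields are an explicit per-field opt-in
  and are pipe-joined on sheets.
* Exit codes are a pure function of the outcome (0 valid, 1 validation
  errors, 2 usage/configuration, 3 I/O/parse), so shell pipelines can
  branch on them.

## Known limitations

Beyond the empty-string/absent collapse on sheets: no unit conversion or
locale-dependent parsing; no ontology reasoning beyond stored parents; no
auto-repair of invalid values; the reconstruction of a bundle from bare
records cannot resurrect an entity that has no records at all; and the
bundled checklist is an example, not the authoritative MIxS term list —
production use should plug in a curated template, which is exactly what
the templates-as-data design is for.
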