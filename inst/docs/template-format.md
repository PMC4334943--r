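# Template file format

A template is one YAML document describing a metadata checklist: which
collections exist and which fields each collection carries. Standards are
data, not code: swapping a checklist or plugging in an environmental
package is a file edit, never a code change.

## Top level

| key            | type             | meaning                                        |
|----------------|------------------|------------------------------------------------|
| `name`         | string, required | template name                                  |
| `version`      | string           | template version (default `"1.0"`)            |
| `vocabularies` | list of strings  | vocabulary names registered with the template  |
| `collections`  | list, required   | collection entries, order-significant          |

Every vocabulary a `cv_term` field references must appear in
`vocabularies`; the term files themselves are loaded separately (one TSV
per vocabulary, see `?read_vocabulary`).

## Collection entries

| key       | type             | meaning                                             |
|-----------|------------------|-----------------------------------------------------|
| `name`    | string, required | one of `project`, `sample`, `library`, `ep`         |
| `subtype` | string           | library type / package name; required for `library` and `ep`, forbidden otherwise; no spaces or underscores |
| `fields`  | list             | field entries, order-significant                     |

A full template has exactly one `project`, one `sample`, at least one
`library` and at least one `ep` collection, and no two collections share
`(name, subtype)`. A *package file* (for `attach_package()`) uses the same
format but its `collections` list holds only the collections to plug in.

## Field entries

| key          | type              | meaning                                             |
|--------------|-------------------|-----------------------------------------------------|
| `key`        | string, required  | canonical token: lowercase letters, digits, `_`     |
| `label`      | string            | display label, original casing (default: the key)   |
| `type`       | string            | data type tag (below; default `text`)               |
| `required`   | bool              | mandatory in its collection? (default false)        |
| `definition` | string            | free-text definition                                |
| `vocab`      | string            | vocabulary name; required iff `type: cv_term`       |
| `pattern`    | string            | regex source; required iff `type: pattern`; must compile; matched against the full value |
| `units`      | string            | unit annotation shown in the workbook label row     |
| `example`    | string            | example value; for `pattern` fields the synthetic generator uses it as its valid value |
| `multi`      | bool              | may hold several values per entity (default false)  |

Field keys must be unique within their collection. The link key
`sample_name` is reserved (the hierarchy machinery owns it) and cannot be
declared.

## Data type tags

`text`, `integer`, `decimal`, `date` (ISO 8601 extended `YYYY-MM-DD`,
calendar-valid), `time` (`HH:MM[:SS]`, 24-hour), `datetime`
(`date'T'time` with optional `Z` or `+HH:MM`/`-HH:MM` offset), `latitude`
/ `longitude` (decimal degrees, range-checked), `url`
(`scheme://authority` minimum), `email`, `cv_term` (must resolve in the
referenced vocabulary), `pattern` (full-string regex gatekeeper).

## Severity of validation codes

Errors: `missing_required`, `no_samples`, `missing_ep`, `broken_link`,
`unknown_collection`, all level-1 data-type codes (`not_integer`,
`not_decimal`, `not_iso_date`, `not_iso_time`, `not_iso_datetime`,
`out_of_range`, `bad_url`, `bad_email`, `cv_violation`,
`pattern_mismatch`), and the parse codes `duplicate_header`, `blank_id`,
`duplicate_id`, `missing_id_column`, `missing_project`.
Warnings (never fatal): `unknown_key`, `unknown_sheet` — arbitrary extra
fields are part of the capture model and are kept, flagged, not rejected.
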