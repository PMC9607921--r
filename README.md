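# ehr13606

Patient-generated health data — side-effect reports and daily activity
tracked by a mobile app — only becomes clinically useful once it lands in an
institutional record system with its meaning intact. `ehr13606` is an R
toolkit for that path, built on the *dual model* of EN/ISO 13606: a stable
**reference model** (extract → entry → element, each element holding one
typed data value) carries the data, while **archetypes** — declarative
constraint models of clinical concepts — define what a conformant entry
looks like. Local app literals (Spanish finding and severity names) are
normalized to SNOMED CT concept IDs through a JSON mapping config, and the
resulting extracts are inserted into an ontology-based clinical repository
where each concept class is a subclass of an ISO 13606 `ENTRY` class and
each coded concept is an instance of a SNOMED CT metaclass carrying its
concept ID and code URI.

The package is aimed at clinical-informatics teams integrating mobile-app
data into EHR infrastructure, and at anyone who wants a compact, fully
testable model of the dual-model communication pattern.

What it provides:

- **Reference model** (`build_entry()`, `canonicalize()`): extracts, entries
  and elements with coded / date / quantity / text values and deterministic
  canonical form.
- **Archetypes** (`builtin_registry()`, `validate_entry()`,
  `validate_extract()`): two bundled entry archetypes — `side_effect`
  (date, finding, value, severity) and `daily_activity` (date, steps,
  calories, duration) — as JSON documents, plus a closed-content validation
  engine. New concepts are new files, not new code.
- **Terminology** (`load_mapping()`, `resolve_term()`): accent- and
  case-insensitive resolution of app literals to SNOMED CT bindings; an
  unmapped literal is a typed error, never silently uncoded output.
- **Conversion** (`convert_side_effect()`, `convert_activity()`,
  `batch_daily()`): one coded, pseudonymous, content-hash-identified extract
  per record, with per-record failure collection for unattended daily runs.
- **XML wire format** (`write_extract()`, `read_extract()`): bit-stable
  serialization validated against a published XSD
  (`inst/extdata/schema/ehr-extract.xsd`).
- **Ontology repository** (`new_repository()`, `ingest_extract()`,
  `count_report()`, `write_ontology()`): idempotent, atomic ingestion with
  sequential `rc_id` assignment, Turtle persistence, and a
  communicated-extract report.
- **Synthetic cohort** (`study_defaults()`, `generate_cohort()`): a
  62-patient pilot cohort — 12 dropouts, 3 never-users, 47 users, 234
  side-effect and 866 activity records over the window 2020-12-22 to
  2022-04-04 — generated by exact-count construction so the whole pipeline
  runs end to end without real patient data.
- **CLI** (`inst/cli/ehrpipe.R`): `simulate`, `convert`, `validate`,
  `ingest`, `report` as file-to-file stages.

## Worked example

Convert a side-effect report of wakefulness and inspect its coding:

```r
library(ehr13606)
m <- load_builtin_mapping()
x <- convert_side_effect(
  side_effect_record("XR-001", "2021-03-01", "Vigilia", "Severo", "poor sleep"),
  m)
print(x)
#> <ehr_extract> x-34ea8612a7e153b54e2f7933
#>   subject: XR-001   created: 2021-03-01T00:00:00Z
#>   entry [side_effect]
#>     at0001 date = 2021-03-01
#>     at0002 finding = Wakefulness [365930002]
#>     at0003 value = poor sleep
#>     at0004 severity = Severe [24484000]
```

The finding literal resolved to SNOMED CT concept ID `365930002`
(Wakefulness); the severity to `24484000` (Severe). `write_extract(x)`
serializes this to schema-valid XML containing the same codes, and the
extract ID is a content hash, so re-sending the same record later
deduplicates at ingestion.

Run the whole study-scale pipeline and print the communicated-extract
report:

```r
run <- run_study_pipeline(study_defaults(), seed = 1)
print(run$report)
#> Number of extracts communicated
#> EHR archetype    Extracts (N=1100), n (%) Patients (N=47), n (%)
#> Side effect      234 (21.3)             34 (72.3)
#> Daily activity   866 (78.7)             38 (80.9)
print(cohort_accounting(run$cohort$summary))
#> Cohort accounting
#>   allocated    62 (100.0%)
#>   dropouts     12 (19.4%)
#>   never_used    3 (4.8%)
#>   users        47 (75.8%)
#>   ...
```

1100 extracts for 47 users: 21.3% side effects over 34 distinct patients,
78.7% daily activity over 38, with zero conversion, validation or ingestion
failures.

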