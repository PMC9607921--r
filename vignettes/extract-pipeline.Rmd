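---
title: "Communicating app-generated clinical data as standardized EHR extracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Communicating app-generated clinical data as standardized EHR extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehr13606)
```

## The dual model

Mobile health apps accumulate patient-generated data — symptom reports,
step counts — in local, uncoded form: free literals in the user's language,
no shared schema. Integrating that data into an institutional record
system without losing meaning requires a common information model *and* a
common terminology. `ehr13606` implements the dual-model approach of
EN/ISO 13606:

- a **reference model** provides generic record structures: an *extract*
  (the unit of communication for one subject) containing *entries* (one
  observation each) containing *elements* (leaf nodes holding a single
  typed data value — coded, date, quantity or text);
- **archetypes** constrain those structures per clinical concept: which
  elements an entry of a given kind has, their value kinds, units,
  optionality, and which terminology value set a coded element may draw
  from.

Because the constraints live in data (JSON archetype documents under
`inst/extdata/archetypes/`), introducing a new concept means authoring a
new archetype file and, if it has coded elements, extending the mapping
config — no code change. The package deliberately models only the
`EHR_EXTRACT / ENTRY / ELEMENT` slice of the reference model: the two
concepts carried here (side effects; daily activity) are flat entries, so
the intermediate COMPOSITION/SECTION/CLUSTER layers of the full standard
would add structure nothing consumes. Multi-occurrence elements,
archetype specialization and ADL parsing are likewise out of scope;
archetypes here are single-occurrence, closed-content constraint lists.

## The pipeline

One record moves through five stages, each exposed both as a function and
as a CLI command (`inst/cli/ehrpipe.R`):

1. **Terminology resolution.** App literals are matched against the JSON
   mapping config (`load_mapping()`), case-insensitively after Unicode
   Latin-ASCII accent folding and whitespace collapsing — the app stores
   Spanish literals with no casing convention, so `"  Náusea "` and
   `"nausea"` must meet. Each binding is also indexed under its SNOMED CT
   preferred term. Resolution is a pure lookup; a miss raises a typed
   `ehr_unmapped_term` condition. The pipeline never emits an uncoded
   stand-in, which is also why a terminology miss during validation is an
   error rather than a warning: coded interoperability is the point.
2. **Conversion.** `convert_side_effect()` / `convert_activity()` build a
   one-entry extract per record. The extract id is a content hash of
   (subject, archetype, date, payload), so identical records always yield
   identical ids and re-sent batches deduplicate downstream. One extract
   per record (rather than bundling a day's records) keeps retries
   idempotent at record granularity. The free-text `value` element of a
   side-effect entry is optional: it is patient elaboration, not required
   structure. Extracts carry only the pseudonymous app-side subject id;
   the app-to-study link table exists solely on the repository side, so
   communication stays unidirectional and no hospital identifier can leak
   into the wire format.
3. **Serialization.** `write_extract()` emits UTF-8 XML validated by the
   published XSD (`inst/extdata/schema/ehr-extract.xsd`). Output is
   bit-stable: the document is canonicalized first (entries sorted by
   archetype, first date and rc_id; elements in archetype declaration
   order), no write-time timestamps are injected, and attribute order is
   fixed. Byte-identical output is what makes hash-based dedupe and
   re-run-produces-identical-files guarantees meaningful. The XSD is
   XSD 1.0 (the libxml2 validator's ceiling), which cannot express
   kind-conditional attribute rules; the parser enforces on top of schema
   validation that coded values carry conceptId/schemeUri/codeUri,
   quantities carry a unit and a non-negative plain-decimal magnitude, and
   dates are real calendar dates.
4. **Validation.** `validate_extract()` applies the archetypes: required
   elements present, no undeclared elements (closed content — archetypes
   constrain, they do not extend), value kinds and units matching, coded
   values inside their bound value sets. All findings are reported with
   paths; nothing is raised, so a batch report can show every problem at
   once.
5. **Ingestion and reporting.** The repository (`new_repository()`) holds
   an ontology in which each archetype concept is a class subsumed by an
   ISO 13606 `ENTRY` class, and each terminology binding is a class typed
   as an instance of a SNOMED CT metaclass annotated with its concept id
   and code URI. Representing the metaclass pattern as plain `rdf:type`
   links keeps the graph useful without OWL-Full reasoning. Ingestion
   validates, resolves the subject through the link table, and inserts one
   instance per entry with a sequential integer `rc_id`; it is atomic (a
   failure leaves the repository untouched) and idempotent by extract id
   (a re-send returns the original insertion results). `count_report()`
   tallies extracts and distinct patients per archetype; the user
   denominator is passed in by the caller because patients who never used
   the app leave no trace in the repository.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| Activity units | `steps` (count), `kcal`, `min` | conventional units for consumer activity trackers; fixed by the `daily_activity` archetype |
| Date precision | day (ISO 8601) | app records are daily; timestamps (`time_created`) are UTC ISO 8601 with seconds, derived from the record date so serialization stays deterministic |
| SNOMED URI scheme | `http://snomed.info/id/<conceptId>` | the standard SNOMED CT URI form |
| Node ids | `at0001…` by archetype declaration order | deterministic, archetype-scoped; zero-padded 4 digits |
| Percentage rounding | half-up to one decimal (`pct()`) | matches how clinical study tables print shares; R's default banker's rounding would print 6.25% as 6.2 |
| rc_id | monotone integer per repository | smallest scheme satisfying uniqueness and stability under re-ingestion |

## The synthetic cohort generator

`generate_cohort()` emulates a small pilot: an allocated cohort in which
some patients drop out (by reason), some never use the app, and the rest
track activity near-daily while reporting side effects intermittently.
The study-scale defaults (`study_defaults()`) are 62 allocated, dropouts
7/2/2/1 (lack of response, medical, lost to follow-up, personal), 3
never-users — hence 47 users — with 234 side-effect records over exactly
34 users and 866 activity records over exactly 38 users, across
2020-12-22 to 2022-04-04.

Two design choices matter:

- **Exact-count construction.** Totals are partitioned across the
  configured number of reporting users (each gets at least one), then
  assigned to dates — activity at most once per user per day, side effects
  unique per (user, date, finding). A feasible configuration therefore
  reproduces its targets exactly for *any* seed, not in expectation;
  infeasible targets (more reporting users than users, more activity
  records than user-days, etc.) fail at config time, before generation.
- **Dropouts and never-users generate nothing.** Whether dropouts
  contributed records before dropping is unknowable from enrollment
  counts alone; attributing all records to the final user set is the
  conservative reading and keeps the accounting self-consistent.

Randomness uses R's Mersenne-Twister via `set.seed()`; a seed plus a
config fully determines the output. Magnitudes are loosely realistic
(steps 300–16000; kcal and minutes derived from steps with Gaussian
noise, clamped at zero).

What the generator does *not* emulate — and hence what green tests do not
show about real data: symptom trajectories with temporal autocorrelation,
severity that tracks treatment cycles, label misspellings or literals
missing from the mapping, app-version drift in record shape, or clock
skew. It exercises the communication contract, not the clinical
epidemiology.

## Numerical and degenerate-input choices

- `pct()` returns 0 for a zero denominator (an empty repository prints
  0.0%, it does not error).
- Canonical entry order breaks ties by (archetype id, first date-valued
  element, rc_id-or-empty); canonicalization is idempotent and
  permutation-invariant, which the test suite checks over random
  permutations.
- Quantity magnitudes serialize as plain decimals with at most six
  fractional digits, trailing zeros stripped, never scientific notation.
- An extract with zero entries cannot be constructed, serialized or
  ingested; an empty batch converts to an empty extract set with an empty
  failure report.
- The Turtle emitter writes one triple per line with `@prefix`
  declarations and standard string escapes — a deliberately small,
  line-diffable subset; the bundled reader parses exactly that subset, and
  the test suite additionally feeds the output to an independent Turtle
  parser.

## Known limitations

- The XML dialect and XSD are this artifact's own strict 13606-flavoured
  schema; third-party 13606 implementations' extract XML is not consumed.
- The bundled mapping is a demonstration fixture: apart from the
  Wakefulness finding (365930002) and the mild/moderate/severe qualifiers,
  its concept ids are marked placeholders, not real SNOMED CT content, and
  the side-effect list itself is illustrative.
- The repository is an in-memory stand-in with Turtle persistence: no
  SPARQL endpoint, reasoning, access control or GUI.
- Occurrence constraints beyond required/optional are not supported;
  neither are archetype slots or specialization.
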