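---
title: "The cohortforge engine: model, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cohortforge engine: model, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortforge)
```

cohortforge turns patient cohort identification into three composable
layers: a star-schema fact store, a declarative pipeline layer ("Logics")
that fills and enriches it, and a boolean query-tree evaluator that reads
it. This vignette documents the model behind each layer, the conventions
and tie-breaks the implementation commits to, what the synthetic-data
generator does and does not emulate, and the design choices made where the
design was genuinely open.

## The fact model

Every piece of clinical content is an *observation fact*: a patient, an
optional encounter, a namespaced concept code, a naive timestamp, and at
most one value payload (`numeric` with unit, `text`, or `flag` with none).
The columns mirror the i2b2 star-schema roles (`concept_cd` →
`concept_code`, `nval_num` → `numeric_value`, `tval_char` → `text_value`,
`start_date` → `start_datetime`).

Conventions worth making explicit:

- **Namespaced codes.** Codes are `SYSTEM:code` strings (`ICD9:250.00`,
  `LOINC:2345-7`, `LOCAL:50931`, `DERIVED:LastHbA1c`). Bare codes from
  different terminologies can collide in one fact table; the namespace
  removes that ambiguity and is enforced at insertion.
- **Naive timestamps, canonical text form.** EHR extracts are almost
  always source-local without timezone. Timestamps are normalized to
  `YYYY-MM-DDTHH:MM:SS`; the fixed width makes lexicographic order equal
  chronological order, so no timezone arithmetic ever happens. A bare date
  means midnight.
- **Insertion order is the universal tie-break.** Every fact gets a
  monotone `row_id`. "Last value" on a day with two measurements, chart
  ordering, and first-match timestamps are all decided by `(timestamp,
  row_id)` — deterministic without inventing clinical precedence.
- **Atomic batches.** `insert_facts()` is all-or-nothing with row-level
  error messages naming the offending field; there is no partial batch
  state to reason about.
- **Closed time windows.** A query window `[start, end]` includes both
  endpoints. Value predicates other than `exists` apply only to numeric
  facts — a text glucose result ("hemolyzed") is never coerced.

The store itself is an in-memory `data.table` with CSV export/import under
a fixed header; it is deliberately a plain, inspectable table rather than
a database dependency. Provider ids are carried on facts but are not a
filterable dimension.

## Logics and the local orchestrator

A *Logic* is a named, typed, path-catalogued pipeline definition. The
catalogue path (`Import/Labs-import`,
`Concept_Hierarchy/Labs-hierarchy`, ...) is purely organizational — a
"logic hierarchy" for finding and grouping pipeline code. The orchestrator
is local and synchronous: `run_logic()` executes immediately and records a
run (status, rows read/written, watermark, ordered log). Scheduling is
accepted as a declarative tag and executed only via an explicit
`run_due()` call; there is no daemon. This trades cloud-managed
orchestration for reproducibility — every run in a test or script is
explicit.

Import semantics that matter for correctness:

- **Watermark increments are strictly greater.** The per-Logic watermark
  stores the maximum watermark-column value over rows actually written;
  re-running on an unchanged source reads zero rows. Rows that *tie* with
  the stored boundary are skipped — avoiding boundary ties (e.g. by using
  a strictly increasing extract timestamp) is the source's responsibility.
  This is the standard trade-off for restartable incremental loads.
- **Per-batch atomicity, not per-run.** A malformed row fails its batch
  whole, but batches already written stay. Large imports keep their
  progress across failures; the run status and log say exactly where to
  resume. The watermark never advances past unwritten rows.
- **The extract is declarative.** A table-source import names a staging
  table, an optional filter expression, and a column mapping that must
  cover `patient_id`, `concept_code`, `start_datetime`. Staging files are
  read with all columns as character, because ICD-9 codes like `250.00`
  are destroyed by numeric parsing. An optional `code_namespace` prefixes
  bare source codes; an optional concept map rewrites local↔standard codes
  at ingest time; an optional per-row `algorithm` plugin (raw row → 0..*n*
  facts) replaces the declarative mapping when transformation logic is
  needed.
- **cdi files are atomic as a whole.** The i2b2-cdi dialect (defined by
  this package: `C` concept rows, `M` mapping rows, `F` fact rows,
  tab-separated) is applied concepts-first against a hierarchy clone; if
  any fact references a concept declared nowhere, neither the store nor
  the hierarchy changes.

## The concept hierarchy

Concepts are forest nodes addressed by `/`-separated paths; a node's
parent is always its path prefix, so cycles are impossible by
construction. Folder nodes carry no code. `expand_concept()` returns the
sorted codes of a node and all descendants — querying `Labs` implicitly
matches every lab leaf. Local-code mappings graft a local child under
*every* path bearing the standard code; a standard code that appears at
several paths therefore expands identically through each occurrence.
(That multi-path behavior is an interpretation: mapping under only one
occurrence would make expansion depend on which path a user happens to
query.) Paths are case-sensitive and matched exactly after whitespace
trimming; a writer option emits the `\`-separated native i2b2 dialect.

## Derived concepts

Derived concepts materialize computations as ordinary facts under
`DERIVED:<name>`, so the query engine needs no special casing — filtering
on a derived flag uses the same path as filtering on a lab. Definitions
are planned topologically over their "reads output of" graph (name-order
tie-breaks make plans deterministic); any cycle refuses the whole plan
before anything executes, naming the cycle. Recomputation replaces the
def's prior output (keyed on `source_logic` + output code), so pipelines
are re-entrant and recomputing on an unchanged store is a fixed point.

Operator semantics:

- `last_value` copies the chronologically last *numeric* source fact per
  patient (value, unit, timestamp). Patients whose source facts are all
  non-numeric are skipped with a log entry rather than failing the run.
- `last_n_consecutive_compare` tests the final *n* measurements — not any
  adjacent *n* — and flags only when the patient has at least *n* and all
  *n* satisfy the comparison. "Last two consecutive glucose > 126" is a
  property of the most recent pair; an earlier qualifying pair does not
  count.
- `any_code_present` flags patients holding any fact in the expanded code
  set (explicit codes, a hierarchy path, or a code prefix), timestamped at
  the earliest match. An empty expansion is a configuration error — the
  criterion author almost certainly mistyped the code set. For the
  diabetes study the code set is the enumerated ICD-9 250.xy family (40
  codes) rather than a store-dependent prefix, so the criterion is
  well-defined even on a store containing no diabetes codes at all.
- `compare_derived` compares a patient's (single) derived numeric value
  against a threshold. All comparisons here and in queries are strict or
  non-strict exactly as written; a last HbA1c of exactly 6.4 does **not**
  satisfy `> 6.4`.
- `script` hands each patient's chart to a registered plugin, which must
  return facts bearing the def's own output code; a foreign code or a
  plugin exception fails the run with nothing inserted.

Derived facts carry no encounter linkage (they typically summarize across
encounters), and each built-in emits at most one fact per patient.
Thresholds are user parameters: the study defaults are glucose 126 mg/dL
and HbA1c 6.4 %, the conventional diagnostic cut-points, and variants
(e.g. a stricter 9.4 % HbA1c cut, or a 120 mg/dL glucose screen) are
expressed by changing the parameter, not the code.

## Query trees

Sibling nodes OR, children AND. Each node's `matched` set is "patients
with at least one fact in the expanded concept satisfying the
operator/threshold within the window"; `cumulative` intersects with the
parent. The cohort is the union of the *leaves'* cumulative sets — the
union-of-path-conjunctions reading, which is the one consistent
interpretation of OR-siblings/AND-children for arbitrary trees (an
internal node is a shared prefix of several conjunctions, not a cohort
terminus; its own count is its cumulative set, not the union of its
subtree). Counts are distinct patients throughout. Negation/exclusion is
deliberately out of scope: complex criteria are expected to be decomposed
into positive constituent filters first.

This reading has two testable consequences, both enforced in the suite:
attrition monotonicity (counts never increase down any root-to-leaf path)
and threshold monotonicity (raising a `>` threshold never increases any
count in that node's subtree). Evaluation is equivalent to brute-force
disjunctive normal form — for every leaf, intersect the matched sets along
its root path, then union over leaves — and the test suite and acceptance
script check exactly that equivalence against an independent linear-scan
oracle on randomized trees.

## What the synthetic generator emulates — and what it does not

`generate_synth_ehr()` emulates the slice of an ICU-style EHR that a
diabetes cohort study consumes: per-patient ICD-9 diagnosis events and
LOINC-coded numeric lab series (serum glucose 2345-7, HbA1c 4548-4) over a
two-year window, staged either as MIMIC-shaped CSV tables
(`diagnoses_icd`, `labevents`), as a cdi interchange file, or direct
inserts. Its defaults are the study conditions: 1000 patients, phenotype
prevalence 0.3, 3–8 glucose and 1–4 HbA1c measurements per patient, 1–4
diagnoses, each case planted into each criterion independently with
probability 0.6 (at least one forced).

Ground truth is crisp by construction — truncated sampling puts case
values strictly on the qualifying side of each threshold and control
values strictly on the other (case last HbA1c in (6.4, 12.0], control in
[4.0, 6.4]; case final glucose pair in (126, 300], control last glucose in
[70, 126]) — so the planted criterion sets are exactly recoverable and any
engine disagreement is an engine defect, not sampling noise. The `fuzzy`
option plants values *exactly at* 6.4 and 126 on some controls to exercise
the strict inequalities. Output is a pure function of the seed:
integer-grid day timestamps and quantized values (integer mg/dL, 0.1 %)
keep it byte-identical across runs.

What it does not emulate, and what passing tests therefore do not show:
real code-assignment noise (diabetics without 250.x codes, miscoded
controls), units heterogeneity, physiological correlation between glucose
and HbA1c, visit-driven measurement timing, or missingness mechanisms. A
perfect recovery here validates the *engine* — import fidelity, derived
semantics, query algebra — not the clinical sensitivity/specificity of the
criteria on real data.

## Validation design and problem sizes

The test suite validates each operation against an independent brute-force
oracle (linear scans, exhaustive tree walks, per-patient sort-slice-compare,
DNF enumeration) rather than against the implementation's own machinery.
The standing validation studies use: 200 randomized query trees (depth ≤ 4,
branching ≤ 3) over stores of 20–250 patients for the query-oracle
equivalence; 500 patients for the derived-operator brute-force comparison
(fuzzy mode on); the full n = 1000 / prevalence 0.3 planted-cohort study
for end-to-end recovery; and a 60-patient dataset for the three-way
ingestion-path equivalence and watermark checks. These sizes give every
code path multi-batch, multi-criterion coverage while keeping the suite
fast enough to run on every change.

## Known limitations

- No negation or temporal-sequence operators in query trees beyond the
  per-node window.
- Watermark ties at the boundary are skipped, not detected.
- The store is in-memory; persistence is the CSV/TSV surface, not a
  transactional database. Millions-of-rows imports work but are bounded
  by memory.
- The `script` plugin contract is per-patient and synchronous; there is no
  distributed execution, and machine-learned derived concepts enter only
  through that hook.
- Concept-hierarchy ingestion is TSV; extraction from a terminology server
  (e.g. UMLS) is upstream of this package.
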