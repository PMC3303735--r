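---
title: "Methods: a desk-scale oncology research warehouse"
author: "oncodw contributors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale oncology research warehouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodw)
```

`oncodw` models the data backbone of a hospital translational-research
platform for breast cancer: pathology reports are mined for coded content,
specimens are anonymized into a biobank, and everything is merged into a
star-schema warehouse that supports ontology-driven cohort queries and two
analysis plug-ins.  This vignette explains the models and procedures, the
parameters that matter, the numerical and design choices made where the
design was genuinely open, and what the synthetic test harness does and does
not demonstrate.

## The warehouse model

The warehouse is a star schema: one `facts` table of coded observations and
four dimensions (`patients`, `visits`, `providers`, `concepts`).  A fact's
unique key is *(patient, visit, concept, date, instance)*; re-inserting a
key replaces the stored row.  Last-wins replacement was chosen so that
reloading corrected source data is safe and the whole ETL is idempotent —
re-running sync and load with unchanged sources leaves every count
unchanged.

Concept hierarchy is carried entirely by the path string: backslash
delimited, with leading and trailing delimiter, and `level` equal to the
number of segments.  Because every path ends with the delimiter, a plain
string-prefix test is automatically segment-aligned (`\A\BC\` is *not*
under `\A\B\`), which makes hierarchical query expansion a one-line
operation and keeps the oracle in the test suite genuinely independent (it
re-derives the relation by comparing segment vectors instead).

Dates are ISO-8601 strings at day precision throughout; the source systems
being modelled do not expose reliable sub-day timestamps, and day precision
keeps the delimited exports diff-able.

## The ontology

The concept dimension combines two parts:

* a *terminology subtree* — the packaged fixture is a synthetic ~40-term
  lexicon of breast-lesion morphology under a "Neoplasm and hamartoma"
  root.  Its codes follow the axis-letter + 5-digit surface form of SNOMED
  morphology codes but are lexicon entries, not assertions about any SNOMED
  release.  `extract_view()` plays the role of a subtree-extraction call
  against a terminology service, and an optional OWL (RDF/XML) reader
  accepts subclass hierarchies in the format such services produce.
* an *internal hierarchy* for demographics, TNM, biomarkers and the biobank
  branch.

Concept *names* (not term ids) form the path segments, because the path is
the human-browsable tree; the term id is kept as `concept_code`.  Duplicate
sibling names are rejected rather than silently suffixed — silent
disambiguation would make two differently-coded concepts
indistinguishable in the browse tree.

TNM is decomposed into three concepts (one per T/N/M component) rather than
one combined code: component-level queries ("all N+ patients") are the
common case, and the combined serialized stage is recoverable from the
extraction XML.  Of the biobank meta-attributes, `project` and
`sample_type` are promoted to queryable concepts while `creation_date` and
`description` stay fact annotations: the former are closed vocabularies a
researcher filters on, the latter are free text.

## Report extraction

Reports are produced by a data-entry process, so they have a stable
skeleton: a metadata preamble, then labelled sections.  The pipeline is a
two-stage pattern system — a sectionizer, then per-field regular
expressions applied **only** to the coded diagnosis section.  Narrative
anamnesis text never reaches the field extractors; the synthetic templates
deliberately plant decoy values (an in-lexicon code, a conflicting Ki-67
percent, a TNM stage) in the anamnesis to keep this restriction honest.

Field conventions:

* percents (ER, PR, Ki-67) must lie in [0, 100]; anything larger is a range
  error rather than a silently clamped value;
* HER-2 is the 0/1+/2+/3+ immunohistochemistry score;
* TNM follows a closed grammar (optional `c`/`p`/`yp` prefix; T in
  X, 0, is, 1, 1a–1c, 2, 3, 4, 4a–4d; N in X, 0, 1, 1a, 2, 2a, 3; M in
  X, 0, 1) and the serialized form round-trips through the parser;
* hormone receptors reported qualitatively ("positive"/"negative") are kept
  as qualitative status — mapping them to sentinel numbers like 100/0 would
  contaminate numeric queries;
* when a field is mentioned twice inside the diagnosis section the first
  mention wins and an ambiguity warning is signalled (the second mention is
  far more often boilerplate than a correction);
* English is the template default with Italian header and label aliases in
  the configuration, and dates are accepted as ISO or day-first numeric.

The XML output mirrors a fixed element order (`document` > `name`, `date`,
`type`, `number`, receptor values, `Ki67`, `c-erb_B2`, `grade`, `state`,
`snomed` with repeated code/name pairs) and is validated against the
packaged XSD on read.  The writer uses the conventional spelling
`progesterone_receptors`; the reader and the schema also accept the
historical `progesterone_recoptors` spelling seen in legacy documents.
Pattern-shaped codes missing from the lexicon are reported separately by
`extract_snomed()` but dropped from the structured record (with a message):
the record must satisfy the schema, and the ETL re-checks codes against the
concept dimension anyway.

## Anonymization

A barcode payload is `FSM-BB-` + 10 characters of Crockford base-32 + a
mod-37 check character.  The alphabet excludes I, L, O and U, so the
payload cannot contain the letter sequences most names are built from by
accident — but the generator does not rely on luck: `new_barcode()` accepts
a deny-list of identifier strings and redraws until the payload shares no
length-4 substring with any of them.  The sync operation feeds it every
identifier field in the pathology-unit table, making PHI-freedom a property
*by construction*.

The lookup table is the only store that may contain source patient ids.  It
holds two maps: payload ↔ patient id, and patient id ↔ warehouse pseudonym.
The pseudonym map is an extension of the minimal design: the warehouse
needs *some* patient key, and using the source id would leak it into every
export.  Pseudonyms are `PT-` plus six random digits — digits only, so they
cannot collide with alphabetic name fragments either.  Store segregation is
realized as a separate directory with its own loader; process-level
isolation is an operational matter, documented rather than enforced.

## ETL

Sync is incremental: a watermark timestamp plus a processed-id set make it
safe to re-run at any cadence (the real-world system syncs every few
minutes and merges weekly; here scheduling is explicit calls, which is what
makes the layer testable).  Non-consented specimens are skipped — no sample
without research consent ever reaches the biobank store or the warehouse —
and malformed rows are quarantined with a log entry instead of aborting the
batch.

The load maps: HIS visits to the visit dimension; sex and vital status to
demographic facts dated at the first visit; each extraction result to one
fact per SNOMED pair, three TNM component facts, and numeric biomarker
facts (units `%` where applicable; qualitative receptor status becomes a
text fact); each consented sample to a material fact (with the free-text
description as its annotation) plus project and sample-type facts.  Facts
are attached to the visit whose date window contains the observation date,
falling back to the patient's first visit.  Instance numbers are assigned
deterministically within each key group, so repeated loads regenerate
identical keys.

## Queries

Panel semantics: OR within a panel (over the hierarchical expansion of each
item), AND across panels, per-panel inversion against the patient
dimension.  Value and date constraints bind to the same fact that matched
the concept — "Ki-67 ≥ 20" means *a Ki-67 fact with value ≥ 20*, not "has
Ki-67 and, somewhere, a large number".  Value constraints require the
panel's expansion to reach at least one biomarker concept; constraining a
purely categorical branch is a type error rather than an empty result,
because the empty result would be indistinguishable from a legitimate
no-match.  Queries deduplicate at patient level (the platform's unit of
analysis is the patient, not the visit).

## Plug-ins

`biobank_info()` joins a patient set to the sample store through the
segregated lookup (authorization required) and emits sample rows without
patient identifiers.

`kaplan_meier()` implements the product-limit estimator directly — the
estimator is the deliverable here, so it is written out rather than
delegated; the `survival` package serves as an independent reference in the
test suite, where agreement is required to 1e-12.  Conventions: censored
observations at an event time remain at risk for that event; the median is
the first event time with S ≤ 0.5 and is undefined if the curve never
reaches 0.5.  Greenwood standard errors and a two-group log-rank test are
available but off by default.  Overall survival is the endpoint; the index
date is the patient's first diagnosis fact under the SNOMED branch, and
patients without one are excluded rather than given an arbitrary index.

## The synthetic cohort

The generator emulates the study conditions of the platform's real
deployment: a breast-cancer cohort accrued over 2001–2011 in which 393 of
6,713 patients (≈ 5.9%) had at least one biobanked sample — that ratio is
the default `biobank_fraction`.  Each patient gets 1–5 visits, 1–2
pathology reports (rendered as sectioned text from the ground-truth
record), an 18% chance of death with the death date beyond the last visit,
and, if biobanked, 1–3 specimens with a 92% consent rate.  Biomarker
distributions follow the field's shape rather than any fitted model:
ER/PR percents have a point mass at zero and are otherwise uniform, with a
minority recorded qualitatively; Ki-67 is a uniform-ish percent; HER-2
scores are skewed toward 0/1+; TNM components are drawn from their closed
vocabularies.  All randomness flows from one seeded stream, so a seed
reproduces every artifact byte for byte.

Donor names are syllable-generated and filtered, at generation time,
against the package's complete export vocabulary, so a leak-scan hit in an
export can only be a genuine leak, never a lexical coincidence between a
made-up name and a domain word.  The names exist solely to exercise the
anonymization layer and never enter any exported store.

What passing tests on this cohort show — and what they do not: the
generator renders reports from the same structural conventions the
extractor's default configuration expects, so 100% field accuracy on the
clean corpus demonstrates internal consistency of the pipeline (as a
validation against a data-entry-generated report format), not performance
on free-dictation clinical text; heavy-noise runs show graceful degradation
(fields are dropped, never mis-read), which is the relevant failure mode
for template drift.  Likewise the cohort is a test harness, not an
epidemiological model: survival times and biomarker joint distributions are
plausible but not calibrated to any population.

## Problem sizes and numerical notes

The test suite validates at the scale the design targets: the query oracle
equivalence runs 200 randomized definitions against a 500-patient cohort;
conservation is checked for 10 seeds at 40 patients; the XML round-trip
covers 500 randomized records; the leak scan uses a 1,000-patient cohort;
the estimator comparison covers 100 randomized survival datasets.  The
acceptance script measures extraction accuracy on a 100-report corpus.  All
arithmetic is exact except the survival curve (floating products compared
at 1e-12) and Greenwood errors (1e-8 against the reference).  Degenerate
inputs are defined rather than accidental: an empty warehouse yields all-zero
counts, an unknown query path yields an empty expansion, an all-censored
cohort yields S ≡ 1 with undefined median, and a fact whose foreign keys do
not resolve is an error naming the key unless stub auto-registration is
explicitly requested.

## Known limitations

* The extractor handles the sectioned, data-entry-generated report family
  only — no negation scope, temporality or free-dictation robustness.
* Store segregation is by location and loader, not by process or
  cryptography; the authorization flag models a gate, not a security
  mechanism.
* The scheduling of sync and merge is the caller's responsibility; there is
  no daemon.
* Ontology versioning, cross-terminology mapping and live terminology
  services are out of scope; the packaged tree is a fixture.
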