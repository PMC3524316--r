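---
title: "Provenance-aware querying of proteomics experiment metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Provenance-aware querying of proteomics experiment metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provdash)
```

## The model

`provdash` organizes experiment metadata around a small provenance
ontology. Three fixed roots come from the W3C PROV-O vocabulary —
`Activity` (things that happen: the experiment, its run groups,
perturbations), `Entity` (things that exist: samples, organisms, cell
lines, bait genes) and `Agent` (responsible parties) — and every domain
class extends exactly one of them through a single-inheritance hierarchy.
Each queryable class ("facet") owns a set of instance values; a record's
metadata is one value per facet. Instances can additionally be linked by
typed relations from a controlled vocabulary (`hadRole`, `used`,
`wasAttributedTo`). These instance-level assertions encode domain facts
that hold across the whole corpus, e.g. that the bait gene EPHB2 has only
ever been used in the HCT116 cell line. Relations are deliberately stored
at the instance level only; class-level relation schemas could be derived
but are not materialized, because all downstream behavior (filtering,
propagation) consumes instance pairs.

Assumptions worth stating explicitly:

* the class graph is a tree (multiple inheritance is rejected at load
  time);
* each instance belongs to exactly one most-specific class;
* labels are compared case-insensitively after whitespace normalization
  and stored in canonical first-declared form. Metadata transcribed by
  humans mixes spellings ("Homo Sapiens" vs "Homo sapiens"); treating
  case as non-significant is the only reading under which such variants
  denote the same value. The packaged vocabulary keeps the verbatim
  spelling "Epilast stem cell" (likely a transcription of "Epiblast") so
  fixture values remain traceable;
* relations are symmetric for lookup: `x related-to y` answers queries
  from either end. Consequently ontology admissibility in smart filtering
  constrains both directions (selecting HCT116 narrows bait genes to
  EPHB2 just as selecting EPHB2 narrows cell lines).

## Serialization

The ontology round-trips through standard Turtle: classes as
`rdfs:Class` with `rdfs:subClassOf` chains and `rdfs:label`s, instances
via `rdf:type`, relations as direct triples with `prov:` predicates. One
serialization dialect keeps round-trip tests bit-stable;
`load_ontology(save_ontology(o))` is the identity on valid ontologies and
is property-tested over randomly generated ones. The reader is a
purpose-built tokenizer/parser for exactly these constructs; emitted files
are verified against an external RDF parser in the test suite, so the
subset stays honest Turtle rather than a private dialect.

## Query semantics

A pattern is an ordered list of equality conditions joined by binary
AND/OR connectives. Mixed chains are folded **left to right with no
precedence**: `((c1 op1 c2) op2 c3) …`. This choice is genuinely open —
flat connective chains are ambiguous — and left-to-right matches how an
interactive builder appends conditions incrementally: each new connective
combines with *everything selected so far*. The translated query prints
the full parenthesization, so the reading is auditable in every emitted
statement, and `evaluate()` (vectorized fold), `execute_translated()`
(recursive-descent evaluation of the emitted clause) and the test suite's
per-record oracle are held to identical match sets on thousands of
patterns.

Only `=` is supported; the condition container carries the operator as an
extension point, but every benchmark pattern is an equality and adding
ranges or negation would change the smart-filter guarantees below.

## Smart filtering

Given a partial pattern, the candidate values offered for a facet `C` are

```
{ v : v co-occurs with the current selections }  ∩  { v : v is ontology-admissible }
```

* **Co-occurrence** uses the *conjunction* of all selected conditions,
  regardless of the pattern's connectives. Under OR, no candidate could
  ever empty the result, so a disjunctive reading would make "only offer
  values that return results" vacuous; the conjunctive reading is the one
  that gives the feature its pruning power. This is a documented decision,
  not something the interface semantics force.
* **Ontology admissibility** intersects, for every selected value that
  carries relation assertions toward `C`, the related instances. Selected
  values with no assertions toward `C` (and values absent from the
  ontology altogether) impose no restriction.
* **Self-exclusion**: when editing an existing condition on `C`, that
  condition is removed from its own filtering context, so the current
  value always remains selectable — standard faceted-search behavior.

These rules give two testable guarantees: *soundness* (every offered
value, appended with AND, yields ≥ 1 match) and *completeness* (every
value that yields ≥ 1 match and is not ontology-excluded is offered).
Both are checked exhaustively over every prefix of the seven benchmark
patterns, every facet, every value. Adding a conjunct never enlarges a
candidate set (monotonicity), and empty candidate sets are valid output,
not errors.

## Constraint propagation

When the user edits one condition, other conditions are repaired against
the changed value's relations: a now-incompatible value is replaced if
exactly one related instance exists for that facet (CTNNB1 → EPHB2
rewrites the cell line to HCT116), and cleared to a pending slot if zero
or several do — the system never guesses among alternatives. Conditions
on unrelated facets, and compatible current values, are untouched.
Pending slots render as empty values and must be filled (or dropped)
before evaluation.

## The synthetic store

`generate_store()` emulates the metadata shape of a proteomics core
running AP-MS and shotgun expression workflows: the default conditions
are 7 projects, 1,000 experiment records, seed 42, three files per
record, and the nine-facet vocabulary of `default_vocabularies()`.
"Not Applicable" is an ordinary perturbation value (untreated runs are
queried by it), not a missing-data marker. Records take one value per
facet, mirroring one-value-per-drop-down composition. Projects receive
experiments by a seeded weighted draw so group sizes are uneven, which
exercises per-project result tabs.

Generation is a pure function of the spec: values are drawn uniformly per
facet, hard constraints (by default the ontology's own relation
assertions, e.g. every EPHB2 record gets cell line HCT116) are then
enforced, and a deterministic coverage patch guarantees every vocabulary
value appears at least once — patched rows are chosen so no constraint is
re-violated, and subject-side facets are patched before re-enforcement so
the pass terminates. Identical specs reproduce the store bit for bit.

What the generator does *not* emulate: free-text and misspelled metadata
beyond case variation, missing values, multi-valued attributes,
per-project vocabulary drift, and any correlation structure beyond the
declared hard constraints. Passing tests therefore demonstrate the
engine's logic, not robustness to dirty institutional data; a real
deployment would put curation between the LIMS and the store.

## Numerical and degenerate-input choices

* Candidate sets, instance listings and result groups are returned in
  deterministic order (case-folded lexicographic via radix sort, or
  project id), independent of locale.
* The empty pattern matches every record; the empty candidate set and the
  empty result set are ordinary values.
* Saved-query timestamps are UTC ISO 8601 with microseconds; re-saving
  bumps `updated_at` strictly even when two saves fall inside one clock
  tick. Catalog writes go through a temp file and an atomic rename, so a
  crash loses at most the in-flight save.
* A condition on an unmapped class fails at translation time, before any
  record is touched, for both execution routes.

## Problem sizes

The test suite and the reproduction script use the default 1,000-record
store for oracle equivalence (seven benchmark patterns plus 200 random
ones), exhaustive smart-filter checks over all benchmark-pattern
prefixes, 100 random ontologies and 500 random patterns for round-trip
properties, and a 50,000-record store (seed 7) for the scalability smoke
with oracle cross-checks on a 5,000-record subsample. These sizes give
full vocabulary coverage and non-vacuous exhaustive checks while keeping
a complete run in the low minutes on one core.

## Limitations

* One active data source per session; federation across stores is not
  implemented.
* No OWL reasoning: subsumption is the explicit hierarchy only, and no
  cross-links to GO/PRO/OBI/EFO are attempted.
* `link_out()` is a URL stub; there is no live LIMS or LabKey
  connectivity, and no authentication — the saved-query catalog records a
  free-text creator label and sharing is file export/import.
* No numeric ranges, negation or free-text search in patterns.
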