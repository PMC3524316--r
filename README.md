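# provdash

A provenance-aware query environment for proteomics experiment metadata.

Core facilities in 'omics centers accumulate experiments across dozens of
projects and workflows — affinity-purification mass spectrometry (AP-MS) for
protein complexes, shotgun expression proteomics for unbiased
identification — but the contextual metadata that makes those datasets
comparable (organism, cell line, bait gene, perturbation, run group, …)
usually lives in per-project silos or lab notebooks. `provdash` treats that
contextual metadata as *provenance*, models it with an ontology that
extends the W3C PROV-O core classes (`prov:Activity`, `prov:Entity`,
`prov:Agent`), and turns it into a cross-project query surface for
researchers rather than database specialists.

The package provides:

* **Ontology handling** — load, validate, and save a PROV-O-extending
  experiment-metadata ontology in Turtle: a single-inheritance class
  hierarchy rooted at the three PROV-O cores, instance values per class,
  and typed instance-level relations (`hadRole`, `used`,
  `wasAttributedTo`) such as *bait gene EPHB2 hadRole cell line HCT116*.
* **Ontology-to-store mapping** — a declarative, injective class→column
  mapping (YAML) with a validation report instead of runtime surprises.
* **A boolean query engine** — patterns are ordered equality conditions
  joined by binary AND/OR connectives, evaluated as a left-to-right fold
  with no operator precedence: `((c1 op1 c2) op2 c3) …`. Translation emits
  a parameterized, explicitly parenthesized SQL-style query; an independent
  executor parses and runs that emitted text, so the two routes
  cross-check each other. Results are grouped per project, with link-out
  URL stubs into the upstream data-management system.
* **Smart filtering** — for each facet, the candidate values offered next
  are the intersection of data co-occurrence (values appearing in at least
  one record matching the conjunction of current selections) and ontology
  admissibility (instance-level relations of the selected values). Every
  offered value is guaranteed to return results.
* **Constraint propagation** — editing one condition repairs dependent
  ones: switching the bait gene from CTNNB1 to EPHB2 rewrites the cell
  line to HCT116 (the only cell line EPHB2 is related to); when several
  values remain compatible the condition is cleared, never guessed.
* **A saved-query manager** — named, dated, re-executable patterns in a
  human-readable YAML catalog with atomic writes.
* **A seeded synthetic generator** — reproducible AP-MS / shotgun
  expression metadata stores honoring the ontology's hard constraints,
  so everything above is testable end to end.
* **A CLI** — `inst/cli/provdash` with `generate`, `query`, `suggest` and
  `saved` subcommands (JSON output, query translation `--explain`, session
  log of executed queries).

## Worked example

```r
library(provdash)

o   <- load_ontology(builtin_ontology_path())   # packaged Turtle ontology
s   <- generate_store(generator_spec(), o)      # 1,000 experiments, 7 projects, seed 42
s
#> <provdash_store> 1000 experiments in 7 projects (9 mapped facets)

p <- parse_dsl("Organism='Homo Sapiens' AND \"Cell line\"='Embryonic stem' OR Perturbation='Dose = 0'")
res <- evaluate(p, s)
res
#> <provdash_results> 321 matching experiment(s) in 7 project(s)
#>   P1 (Project 01): 62
#>   P2 (Project 02): 70
#>   P3 (Project 03): 31
#>   P4 (Project 04): 51
#>   P5 (Project 05): 32
#>   P6 (Project 06): 33
#>   P7 (Project 07): 42
```

321 experiments match the left-to-right reading
`((Organism AND Cell line) OR Perturbation)`: human embryonic-stem records
plus all zero-dose perturbations, grouped into one tab per project.
The translation is auditable — values are bound parameters, never
interpolated:

```r
translate(p, default_config())
#> <provdash_translated>
#>   SELECT experiment_id, project_id FROM experiments WHERE
#>   ((LOWER(organism) = LOWER(?) AND LOWER(cell_line) = LOWER(?)) OR LOWER(perturbation) = LOWER(?))
#>   params: 'Homo Sapiens', 'Embryonic stem', 'Dose = 0'
```

Smart filtering prunes the next drop-down to values that cannot produce an
empty result — after selecting bait gene EPHB2, only its ontology-linked
cell line survives:

```r
smart_filter(parse_dsl("\"Bait gene\"='EPHB2'"), "Cell line", s, o)
#> <provdash_candidates>
#>   Cell line: HCT116
```

`tidy()` and `glance()` give tibble views of any result
(`glance(res)` → `total = 321, n_projects = 7`), and `autoplot(res)` draws
the per-project match counts.

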