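#' Benchmark query patterns Q1-Q7
#'
#' The seven query patterns of increasing connective complexity used to
#' exercise the engine, from a single-condition organism filter up to an
#' eight-condition mixed AND/OR chain. Q1 spells the organism
#' 'Homo Sapiens' and Q3 'Homo sapiens'; value matching is
#' case-insensitive, so both select the same records — the pair doubles as
#' a living check of that rule.
#'
#' @return A tibble with columns `id`, `description` and `dsl` (the pattern
#'   in the [parse_dsl()] text form).
#' @export
example_queries <- function() {
  tibble::tribble(
    ~id, ~description, ~dsl,
    "Q1", "Experiments in any human sample",
    "Organism='Homo Sapiens'",
    "Q2", "Embryonic stem cell line or any human sample",
    "Organism='Homo Sapiens' OR \"Cell line\"='Embryonic stem'",
    "Q3", "Human embryonic stem samples, or zero-dose perturbation, or cytosolic fraction",
    "Organism='Homo sapiens' AND \"Cell line\"='Embryonic stem' OR Perturbation='Dose = 0' OR \"Subcellular Fraction\"='Cytosol'",
    "Q4", "DNMT1 bait in AP-MS, or WNT3A perturbation in bait run group, or RKO cell line",
    "\"Bait gene\"='DNMT1' AND \"Experiment Type\"='AP-MS' OR Perturbation='WNT3A' AND \"Run Group\"='Bait' OR \"Cell line\"='RKO'",
    "Q5", "Protein expression for fly T-cell cultures at 10 ng, or treated cell cultures",
    "\"Experiment Type\"='Protein Expression' OR \"Cell line\"='T-cells (Boom)' AND Organism='Drosophila melanogaster' AND Perturbation='10 ng' OR \"Run Group\"='Treated' AND \"Sample Type\"='Cell culture'",
    "Q6", "POU5F1 bait or embryonic-stem AP-MS, or untreated mouse or endogenous cell cultures",
    "\"Bait gene\"='POU5F1' OR \"Cell line\"='Embryonic stem' AND \"Experiment Type\"='AP-MS' OR Organism='Mus musculus' AND Perturbation='Not Applicable' OR \"Sample Type\"='Cell culture' OR \"Bait Type\"='Endogenous'",
    "Q7", "Protein expression or fly T-cell tagged cultures, untreated APC bait with no-vector-control run group",
    "\"Experiment Type\"='Protein Expression' OR \"Cell line\"='T-cells (Boom)' AND Organism='Drosophila melanogaster' AND \"Bait Type\"='Tagged' AND \"Sample Type\"='Cell culture' OR Perturbation='Not Applicable' AND \"Bait gene\"='APC' AND \"Run Group\"='No Vector Control'"
  )
}
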