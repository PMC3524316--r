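# Built-in proteomics provenance ontology, vocabularies and default
# data-source mapping for the two exemplar workflows: affinity-purification
# mass spectrometry (AP-MS) and shotgun expression proteomics.

#' Default facet vocabularies for AP-MS and shotgun-expression metadata
#'
#' The controlled instance values of the nine queryable metadata facets:
#' experiment type, organism, cell line, bait gene, bait type (how the bait
#' protein is expressed), perturbation, run group, sample type and
#' subcellular fraction. "Not Applicable" is an ordinary perturbation value,
#' not a missing-data marker: shotgun expression runs without treatment are
#' recorded, and queried, with that value.
#'
#' @return Named list mapping facet class name to a character vector of
#'   instance labels.
#' @export
default_vocabularies <- function() {
  list(
    "Experiment Type" = c("AP-MS", "Protein Expression"),
    "Organism" = c("Homo Sapiens", "Mus musculus", "Drosophila melanogaster"),
    "Cell line" = c("Embryonic stem", "Epilast stem cell", "HCT116", "RKO", "T-cells (Boom)"),
    "Bait gene" = c("DNMT1", "CTNNB1", "EPHB2", "POU5F1", "APC"),
    "Bait Type" = c("Endogenous", "Exogenous", "KnockIn", "Tagged", "Untagged"),
    "Run Group" = c("Bait", "Treated", "No Vector Control"),
    "Sample Type" = c("Cell culture"),
    "Perturbation" = c("Dose = 0", "WNT3A", "10 ng", "Not Applicable"),
    "Subcellular Fraction" = c("Cytosol")
  )
}

#' Built-in proteomics provenance ontology
#'
#' Constructs the packaged ontology: the three PROV-O roots, a small domain
#' hierarchy beneath them, the facet vocabularies of
#' [default_vocabularies()], and the instance-level `hadRole` assertions
#' that tie specific bait genes to the only cell line they were ever used
#' in (e.g. EPHB2 to HCT116). These assertions are what make constraint
#' propagation in the query builder possible. DNMT1 deliberately carries no
#' assertions: an unconstrained bait exercises the "ontology places no
#' restriction" path.
#'
#' The same ontology ships as a Turtle file at
#' `system.file("extdata", "proteomics_prov.ttl", package = "provdash")`.
#'
#' @return A [ontology()] object.
#' @export
builtin_ontology <- function() {
  classes <- tibble::tribble(
    ~name, ~parent,
    "Proteomics Experiment", "Activity",
    "Experiment Type", "Proteomics Experiment",
    "Run Group", "Proteomics Experiment",
    "Perturbation", "Proteomics Experiment",
    "Sample", "Entity",
    "Sample Type", "Sample",
    "Organism", "Sample",
    "Cell line", "Sample",
    "Subcellular Fraction", "Sample",
    "Bait gene", "Entity",
    "Bait Type", "Entity",
    "Researcher", "Agent"
  )
  vocab <- default_vocabularies()
  instances <- purrr::imap_dfr(vocab, function(labels, class) {
    tibble::tibble(class = class, label = labels)
  })
  relations <- tibble::tribble(
    ~subject_class, ~subject, ~predicate, ~object_class, ~object,
    "Bait gene", "EPHB2", "hadRole", "Cell line", "HCT116",
    "Bait gene", "CTNNB1", "hadRole", "Cell line", "RKO",
    "Bait gene", "POU5F1", "hadRole", "Cell line", "Embryonic stem",
    "Bait gene", "APC", "hadRole", "Cell line", "T-cells (Boom)"
  )
  ontology(classes, instances, relations)
}

#' Path to the packaged Turtle ontology file
#' @return File path of `proteomics_prov.ttl` inside the installed package.
#' @export
builtin_ontology_path <- function() {
  system.file("extdata", "proteomics_prov.ttl", package = "provdash", mustWork = TRUE)
}

#' Path to the packaged default data-source configuration file
#' @return File path of `default_config.yaml` inside the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "provdash", mustWork = TRUE)
}

#' Default data-source configuration
#'
#' Maps each of the nine queryable facet classes to a snake_case column of
#' the experiment store.
#'
#' @param store_uri Store location recorded in the config (default: a
#'   placeholder the caller overrides at generation time).
#' @return A `provdash_config` object with nine mappings.
#' @export
default_config <- function(store_uri = "store") {
  data_source_config(
    name = "cpb-proteomics",
    store_uri = store_uri,
    mappings = tibble::tribble(
      ~class, ~column,
      "Experiment Type", "experiment_type",
      "Organism", "organism",
      "Cell line", "cell_line",
      "Bait gene", "bait_gene",
      "Bait Type", "bait_type",
      "Perturbation", "perturbation",
      "Run Group", "run_group",
      "Sample Type", "sample_type",
      "Subcellular Fraction", "subcellular_fraction"
    )
  )
}
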