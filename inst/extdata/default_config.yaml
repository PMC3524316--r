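format_version: 1
name: cpb-proteomics
store_uri: store
mappings:
- class: Experiment Type
  column: experiment_type
- class: Organism
  column: organism
- class: Cell line
  column: cell_line
- class: Bait gene
  column: bait_gene
- class: Bait Type
  column: bait_type
- class: Perturbation
  column: perturbation
- class: Run Group
  column: run_group
- class: Sample Type
  column: sample_type
- class: Subcellular Fraction
  column: subcellular_fraction
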