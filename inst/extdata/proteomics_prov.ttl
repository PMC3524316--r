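@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix prov: <http://www.w3.org/ns/prov#> .
@prefix pv: <http://provdash.org/ns#> .

prov:Activity a rdfs:Class ;
    rdfs:label "Activity" .

prov:Agent a rdfs:Class ;
    rdfs:label "Agent" .

pv:Bait_gene a rdfs:Class ;
    rdfs:label "Bait gene" ;
    rdfs:subClassOf prov:Entity .

pv:Bait_Type a rdfs:Class ;
    rdfs:label "Bait Type" ;
    rdfs:subClassOf prov:Entity .

pv:Cell_line a rdfs:Class ;
    rdfs:label "Cell line" ;
    rdfs:subClassOf pv:Sample .

prov:Entity a rdfs:Class ;
    rdfs:label "Entity" .

pv:Experiment_Type a rdfs:Class ;
    rdfs:label "Experiment Type" ;
    rdfs:subClassOf pv:Proteomics_Experiment .

pv:Organism a rdfs:Class ;
    rdfs:label "Organism" ;
    rdfs:subClassOf pv:Sample .

pv:Perturbation a rdfs:Class ;
    rdfs:label "Perturbation" ;
    rdfs:subClassOf pv:Proteomics_Experiment .

pv:Proteomics_Experiment a rdfs:Class ;
    rdfs:label "Proteomics Experiment" ;
    rdfs:subClassOf prov:Activity .

pv:Researcher a rdfs:Class ;
    rdfs:label "Researcher" ;
    rdfs:subClassOf prov:Agent .

pv:Run_Group a rdfs:Class ;
    rdfs:label "Run Group" ;
    rdfs:subClassOf pv:Proteomics_Experiment .

pv:Sample a rdfs:Class ;
    rdfs:label "Sample" ;
    rdfs:subClassOf prov:Entity .

pv:Sample_Type a rdfs:Class ;
    rdfs:label "Sample Type" ;
    rdfs:subClassOf pv:Sample .

pv:Subcellular_Fraction a rdfs:Class ;
    rdfs:label "Subcellular Fraction" ;
    rdfs:subClassOf pv:Sample .

pv:Bait_gene_APC a pv:Bait_gene ;
    rdfs:label "APC" .

pv:Bait_gene_CTNNB1 a pv:Bait_gene ;
    rdfs:label "CTNNB1" .

pv:Bait_gene_DNMT1 a pv:Bait_gene ;
    rdfs:label "DNMT1" .

pv:Bait_gene_EPHB2 a pv:Bait_gene ;
    rdfs:label "EPHB2" .

pv:Bait_gene_POU5F1 a pv:Bait_gene ;
    rdfs:label "POU5F1" .

pv:Bait_Type_Endogenous a pv:Bait_Type ;
    rdfs:label "Endogenous" .

pv:Bait_Type_Exogenous a pv:Bait_Type ;
    rdfs:label "Exogenous" .

pv:Bait_Type_KnockIn a pv:Bait_Type ;
    rdfs:label "KnockIn" .

pv:Bait_Type_Tagged a pv:Bait_Type ;
    rdfs:label "Tagged" .

pv:Bait_Type_Untagged a pv:Bait_Type ;
    rdfs:label "Untagged" .

pv:Cell_line_Embryonic_stem a pv:Cell_line ;
    rdfs:label "Embryonic stem" .

pv:Cell_line_Epilast_stem_cell a pv:Cell_line ;
    rdfs:label "Epilast stem cell" .

pv:Cell_line_HCT116 a pv:Cell_line ;
    rdfs:label "HCT116" .

pv:Cell_line_RKO a pv:Cell_line ;
    rdfs:label "RKO" .

pv:Cell_line_T_cells_Boom a pv:Cell_line ;
    rdfs:label "T-cells (Boom)" .

pv:Experiment_Type_AP_MS a pv:Experiment_Type ;
    rdfs:label "AP-MS" .

pv:Experiment_Type_Protein_Expression a pv:Experiment_Type ;
    rdfs:label "Protein Expression" .

pv:Organism_Drosophila_melanogaster a pv:Organism ;
    rdfs:label "Drosophila melanogaster" .

pv:Organism_Homo_Sapiens a pv:Organism ;
    rdfs:label "Homo Sapiens" .

pv:Organism_Mus_musculus a pv:Organism ;
    rdfs:label "Mus musculus" .

pv:Perturbation_x10_ng a pv:Perturbation ;
    rdfs:label "10 ng" .

pv:Perturbation_Dose_0 a pv:Perturbation ;
    rdfs:label "Dose = 0" .

pv:Perturbation_Not_Applicable a pv:Perturbation ;
    rdfs:label "Not Applicable" .

pv:Perturbation_WNT3A a pv:Perturbation ;
    rdfs:label "WNT3A" .

pv:Run_Group_Bait a pv:Run_Group ;
    rdfs:label "Bait" .

pv:Run_Group_No_Vector_Control a pv:Run_Group ;
    rdfs:label "No Vector Control" .

pv:Run_Group_Treated a pv:Run_Group ;
    rdfs:label "Treated" .

pv:Sample_Type_Cell_culture a pv:Sample_Type ;
    rdfs:label "Cell culture" .

pv:Subcellular_Fraction_Cytosol a pv:Subcellular_Fraction ;
    rdfs:label "Cytosol" .

pv:Bait_gene_APC prov:hadRole pv:Cell_line_T_cells_Boom .
pv:Bait_gene_CTNNB1 prov:hadRole pv:Cell_line_RKO .
pv:Bait_gene_EPHB2 prov:hadRole pv:Cell_line_HCT116 .
pv:Bait_gene_POU5F1 prov:hadRole pv:Cell_line_Embryonic_stem .
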