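# Reconstructed pathogenic/population-associated feature sets for the
# nucleic-acid-binding protein class (catalog v1). Synthetic reconstruction
# from published class-level statements, not a database extract: core/buried
# exposure, aromatic and special residues, strand and (class-specific)
# alpha-helical context, hydrogen-bond sites, phosphosite proximity and
# functional annotations are pathogenic-associated; exposed bins and
# aliphatic/neutral groups are population-associated.
group	feature	association
nucleic_acid_binding	exp_core	pathogenic
nucleic_acid_binding	exp_buried	pathogenic
nucleic_acid_binding	ss_helix_alpha	pathogenic
nucleic_acid_binding	ss_strand	pathogenic
nucleic_acid_binding	aa_aromatic	pathogenic
nucleic_acid_binding	aa_special	pathogenic
nucleic_acid_binding	bond_hbond_intra	pathogenic
nucleic_acid_binding	bond_hbond_inter	pathogenic
nucleic_acid_binding	ptm_near_phosphorylation	pathogenic
nucleic_acid_binding	func_modular_domain	pathogenic
nucleic_acid_binding	func_modified_residue	pathogenic
nucleic_acid_binding	func_binding_region	pathogenic
nucleic_acid_binding	exp_medium_buried	population
nucleic_acid_binding	exp_medium_exposed	population
nucleic_acid_binding	exp_exposed	population
nucleic_acid_binding	aa_aliphatic	population
nucleic_acid_binding	aa_neutral	population
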