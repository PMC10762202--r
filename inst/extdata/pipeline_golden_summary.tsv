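metric	value
n_samples	40
n_snps_tested	400
n_species_tested	30
n_significant_snp_tests	5
n_loci	1
n_locus_snps	5
n_associated_species	1
n_enriched_pathways	0
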