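attribute	value
contig1_bp	3546937
contig2_bp	7823
genome_size_bp	3554760
dna_coding_bp	3153982
dna_gc_bp	2289453
total_genes	3392
protein_coding_genes	3325
rna_genes	67
genes_in_cogs	2764
not_in_cogs	628
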