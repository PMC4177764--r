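phage	accession	size_bp	n_cds	gene_density	coding_percent	avg_product_aa	gc_percent
ZZ1	NC_018087.3	166687	256	1.5	93.9	203	34.41
133	NC_015250.1	159801	257	1.6	95.5	197	39.67
Acj9	NC_014663.1	169947	253	1.5	93.3	208	40.03
Acj61	NC_014661.1	164093	241	1.5	92.5	209	39.01
Ac42	NC_014660.1	167716	255	1.5	94.9	207	36.37
T4	NC_000866.4	168903	278	1.6	97.8	197	35.30
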