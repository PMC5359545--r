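functional_class	trio	species_specific	phenotype_segregation	gene_list
stop_gain	678	454	8	0
start_stop_loss	134	330	0	0
splice_donor_acceptor	2547	88	22	0
exon_deletion	4	1	0	0
frameshift	3602	722	20	1
rare_amino_acid	0	0	0	0
codon_alteration	1462	711	13	0
missense	47534	32038	595	7
splice_branch	0	0	0	0
utr_deletion	0	0	0	0
low_other	89718	59119	859	13
modifier	22064948	13437721	232512	1019
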