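gene_id	tmm_infected	ic	mature_length	molecular_weight_kda	net_charge	enriched_residues
GJ10737	1.368	2.503	35	4.07	12	Arg+Val (51%)
GJ18291	0.316	3.909	61	6.70	25	Lys+Ser (46%)
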