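species	condition	total_reads	mito_reads	rrna_reads	assigned_reads	genes_hit	min_length	max_length	mean_length
D_virilis	infected	109106	5557	25991	55358	5155	40	715	226
D_virilis	naive	119533	6197	22500	62110	4709	40	667	217
D_melanogaster	infected	110578	5998	38910	63555	4735	40	710	242
D_melanogaster	naive	91947	7483	35990	46536	4275	40	580	219
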