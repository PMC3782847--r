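putative_id	reads_infected	reads_naive	ic_printed	homologue	homologue_reads_infected	homologue_reads_naive	homologue_ic
PG00034	17	37	0.477	IM14	68	19	3.162
PG01778	7	0	Inf	Rho1	16	7	2.020
PG02420	2	10	0.208	NA	NA	NA	NA
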