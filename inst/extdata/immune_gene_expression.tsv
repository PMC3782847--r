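species	gene_id	homologue	reads_infected	tmm_infected	reads_naive	tmm_naive	ic_printed	functional_class	note
D_virilis	GJ20666	CG13422	6	0.153	0	0	Inf	recognition	Beta-glucan binding domain
D_virilis	GJ12160	PGRP-SB1	11	0.235	2	0.040	5.864	recognition	PGRP domain
D_virilis	GJ18074	nimB3	2	0.067	12	0.376	0.178	recognition	Nimrod-related
D_virilis	GJ12373	msn	9	0.024	1	0.002	9.595	signaling	Kinase
D_virilis	GJ20603	Pvr	15	0.038	2	0.005	7.996	signaling	Receptor
D_virilis	GJ19441	SPE	3	0.033	15	0.155	0.213	signaling	Protease
D_virilis	GJ22479	Def	53	2.445	0	0	Inf	effector	Antimicrobial peptide
D_virilis	GJ21173	AttC	47	0.818	0	0	Inf	effector	Antimicrobial peptide
D_virilis	Cec2B	CecA1/CecA2	25	1.604	0	0	Inf	effector	Antimicrobial peptide
D_virilis	Cec3	CecC	23	1.475	0	0	Inf	effector	Antimicrobial peptide
D_virilis	GJ22469	Mtk	9	0.660	0	0	Inf	effector	Antimicrobial peptide
D_virilis	GJ19916	Dpt	104	3.812	4	0.138	27.720	effector	Antimicrobial peptide
D_virilis	GJ19917	DptB	39	1.120	3	0.081	13.860	effector	Antimicrobial peptide
D_virilis	GJ20572	AttA	49	0.856	24	0.393	2.177	effector	Antimicrobial peptide
D_virilis	GJ17981	fon	217	1.641	370	2.624	0.625	effector	Coagulation
D_virilis	GJ18607	IM4	79	7.542	151	13.521	0.558	effector	IM
D_virilis	GJ21308	IM10	23	0.350	51	0.727	0.481	effector	IM
D_virilis	GJ19885	IM1	37	3.302	123	10.296	0.321	effector	IM
D_melanogaster	PGRP-SB1	PGRP-SB1	29	0.779	0	0	Inf	recognition	PGRP domain
D_melanogaster	PGRP-SC2	PGRP-SC2	20	0.603	3	0.102	5.891	recognition	Amidase degradation
D_melanogaster	TepII	TepII	188	0.708	31	0.132	5.359	recognition	Tep
D_melanogaster	TepIV	TepIV	37	0.131	13	0.052	2.515	recognition	Tep
D_melanogaster	CecC	CecC	35	1.521	0	0	Inf	effector	Antimicrobial peptide
D_melanogaster	AttC	AttC	252	4.684	2	0.042	111.333	effector	Antimicrobial peptide
D_melanogaster	Dpt	Dpt	343	11.568	24	0.916	12.628	effector	Antimicrobial peptide
D_melanogaster	DptB	DptB	80	2.974	6	0.252	11.781	effector	Antimicrobial peptide
D_melanogaster	IM18	IM18	62	1.403	8	0.205	6.848	effector	IM
D_melanogaster	Mtk	Mtk	380	23.719	52	3.673	6.457	effector	Antimicrobial peptide
D_melanogaster	Dro	Dro	192	4.237	27	0.674	6.283	effector	Antimicrobial peptide
D_melanogaster	IM14	IM14	68	5.101	19	1.613	3.162	effector	IM
D_melanogaster	AttA	AttA	96	2.113	27	0.673	3.142	effector	Antimicrobial peptide
D_melanogaster	IM4	IM4	56	2.194	16	0.709	3.093	effector	IM
D_melanogaster	IM10	IM10	355	6.147	116	2.273	2.704	effector	IM
D_melanogaster	IM1	IM1	247	11.541	82	4.336	2.662	effector	IM
D_melanogaster	AttB	AttB	74	1.428	27	0.590	2.422	effector	Antimicrobial peptide
D_melanogaster	IM2	IM2	139	6.250	62	3.155	1.981	effector	IM
D_melanogaster	Drs	Drs	551	23.817	299	14.627	1.628	effector	Antimicrobial peptide
D_melanogaster	IM3	IM3	330	18.401	188	11.864	1.551	effector	IM
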