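family	chrom	rsid	gene	consequence	aa_change	sift	polyphen	cadd	maf_gnomad	maf_pop	hom_controls
AM-CD	10	rs56226109	FGFR2	missense	S57L	tolerated	benign	22.4	0.0049	0.0065	0/3
AM-CD	10	rs143892520	DMBT1	missense	D560E	deleterious	unknown	12.66	0.015	-	0/3
AM-UC	8	-	DENND3	missense	R487S	deleterious	possibly_damaging	18.83	-	-	1/10
AM-UC	9	rs5794	PTGS1	missense	V481I	deleterious	benign	23.3	0.0072	0.0146	3/10
AM-UC	9	-	WDR38	missense	R51W	deleterious	possibly_damaging	28.4	-	-	3/10
AM-UC	9	rs146651928	CERCAM	missense	Q187E	deleterious	probably_damaging	22.9	0.0006	0.0005	3/10
AM-UC	15	-	AAGAB	missense	D312N	tolerated	possibly_damaging	25.8	-	-	0/10
DR	2	rs148167737	MAP4K3	missense	A410T	tolerated	benign	23.9	0.0008	-	1/6
DR	2	rs377671536	MAP4K4	missense	Q515E	tolerated_lc	possibly_damaging	23.3	0.0002	0.0005	0/6
DR	9	rs3739740	NIPSNAP3B	missense	K154E	deleterious	possibly_damaging	27.7	0.0267	0.0347	1/6
DR	15	rs185529473	WHAMM	missense	R725W	deleterious	possibly_damaging	29.5	4.47e-05	-	0/6
DR	15	rs61752778	ADAMTSL3	missense	P821S	tolerated	probably_damaging	24.4	0.0163	0.0091	0/6
DR	15	rs61731243	AKAP13	missense	E1106G	deleterious_lc	benign	16.55	0.0415	0.0267	0/6
DR	15	rs55798315	LRRK1	missense	P543S	deleterious	probably_damaging	29.8	0.0044	0.0171	1/6
AJ	4	rs112033303	COQ2	stop_gained	R22X	unknown	unknown	23	0.0166	0.0304	0-1/3
AJ	2	rs138440701	IL36B	missense	I110T	deleterious_lc	benign	3.083	0.013	0.0222	0-1/3
AJ	9	rs34552775	C5	missense	L354M	deleterious	possibly_damaging	25	0.0054	0.0044	0-1/3
AJ	19	rs75841596	PALM3	missense	D604N	deleterious	possibly_damaging	26.8	0.0245	0.0319	0/3
AJ	19	rs75251420	MYO9B	missense	V1700M	deleterious	benign	23.9	0.0014	0.0024	0/3
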