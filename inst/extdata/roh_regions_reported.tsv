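family	case_set	chrom	start_bp	end_bp	length_mb	n_snps	in_sib_set
AM-UC	UC_sibs	1	37013031	46037357	9.0	772	TRUE
AM-UC	UC_sibs	8	137523046	142950775	5.4	612	TRUE
AM-UC	UC_sibs	9	124704304	141022295	16.3	1539	TRUE
AM-UC	UC_sibs	15	54343188	79365780	25.0	2154	TRUE
AM-UC	UC_sibs	15	51663597	52878719	1.2	57	FALSE
DR	CD_cases	2	220753783	222044974	1.3	141	FALSE
DR	CD_cases	16	48846170	51468005	2.6	359	FALSE
AJ	CD_sibs	2	183467456	190452586	7.0	451	FALSE
AJ	CD_sibs	4	53383129	54396077	1.0	55	FALSE
AJ	CD_sibs	12	22890730	26139522	3.2	361	FALSE
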