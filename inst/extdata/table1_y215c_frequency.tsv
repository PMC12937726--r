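population	n_subjects	maf_per_100k	n_carriers	recomputable
European	349976	1444	5054	TRUE
African	36268	312	113	TRUE
Latinos	9570	170	16	FALSE
Asian	12238	57	7	TRUE
South Asian	8960	1	0.1	TRUE
Total	434616	1267	5507	TRUE
TOPMED	264690	924	2447	TRUE
UK Biobank	54512	1626	951	FALSE
Icelanders	35559	1534	545	FALSE
FMBA	120762	2571	3105	TRUE
RUSEQ	12976	1318	171	TRUE
Genomed	37620	1881	708	FALSE
RSMU	4657	1181	55	TRUE
RUSS-AGE	290	2411	7	FALSE
Longevity	200	2500	5	TRUE
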