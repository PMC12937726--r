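variant_id	gene	uniprot	protein_position	aa_change	consequence	beta	p_value	polyphen2	maf_iceland_100k	maf_dbsnp_100k
rs8176743	ABO	P16442	234	G/S	missense	0.351	5.356 × 10^−105	0.168	6.488	10587
rs8176746	ABO	NA	265	L/M	missense	0.35	8.358 × 10^−105	0.09	6.496	10589
rs8176747	ABO	NA	267	G/A	missense	0.35	9.314 × 10^−105	0.003	6.497	10589
rs750712925	ACE	P12821	45	G/R	missense	−1.288	6.8 × 10^−15	0.142	82	1.9
rs3730025	ACE	NA	244	Y/C	missense	−1.217	3.306 × 10^−291	0.998	1.534	924
rs757694144	ACE	NA	482	R/P	missense	−1.349	1.50 × 10^−7	0.246	34	0.4
rs372416620	ACE	NA	1243	V/I	missense	0.371	6.70 × 10^−9	0.061	469	5.7
rs145825553	ADAMTS13	Q76LX8	421	R/C	missense	0.394	2.40 × 10^−8	0.994	334	45
rs771742994	BCAS3	Q9H6U6	480	S/I	missense	−1.162	2.20 × 10^−12	0.991	88	5.7
rs117181531	DDX42	Q86XP3	754	S/I	missense	0.429	4.50 × 10^−9	0.114	317	180
rs117595304	GBGT1	Q8N5D6	66	Y/C	missense	−0.363	1.20 × 10^−9	0.817	457	311
rs367887663	MFSD6L	Q8IWD5	323	H/D	missense	0.505	3.50 × 10^−8	0.902	166	7.2
rs1352161075	MILR1	Q7Z6M3	159	T/I	missense	0.376	1.20 × 10^−10	0.035	539	3.4
rs201723860	SMARCD2	Q92925	201	T/M	missense	0.478	7.00 × 10^−8	0.985	242	15
rs750512077	STRADA	Q7RTN6	215	R/H	missense	−0.405	2.80 × 10^−9	0.999	352	1.5
rs370863314	TANC2	Q9HCD6	2015	R/P	missense	0.479	8.20 × 10^−9	0.066	232	10
rs780968826	TEX2	Q8IWB9	375	E/K	missense	0.366	9.00 × 10^−10	0.003	486	0.5
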