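row	gene	cdna	variant_id	1737	1340	181	614	615	HSY004	HWY602	JQW970	KJB939	OTS421	OTX780	SRZ900	TXM676	VYA317	XLK932	maf_gnomad_100k	maf_fmba_100k
1	CD34	c.398C>T	rs148688256	-	-	-	-	-	Het	-	Het	-	-	-	-	-	-	Het	192	1020
2	TMEM240	c.454G>A	rs146206869	-	-	-	Het	-	-	-	-	-	-	Het	-	Het	-	-	3364	2825
3	CHST15	c.98C>T	rs34639461	-	Het	-	-	-	-	-	-	-	-	Het	-	Het	-	-	2984	2880
4	ACCSL	c.133G>A	rs11037840	-	-	-	-	-	-	Het	Het	-	-	-	Het	-	-	-	450	1220
5	MYRFL	c.2072C>T	rs61754226	Het	-	-	-	-	-	-	-	-	-	Het	-	-	-	Het	690	620
6	TMCC3	c.564G>A	rs149007412	-	Het	-	-	-	-	-	Het	-	-	-	-	-	Het	-	674	1270
7	LTBP2	c.4769T>C	rs139932140	-	-	-	-	-	-	-	Het	-	-	-	Het	-	-	-	773	1805
8	RPAP1	c.146C>T	rs112536229	Het	-	Het	-	-	-	-	Het	-	-	-	-	-	-	-	1157	1680
9	CFAP161	c.850C>T	rs2279997	-	-	-	-	Het	-	Het	Het	-	-	-	-	-	-	-	1080	1290
10	PKD1	c.10529C>T	rs45478794	Het	-	-	-	-	-	-	Het	Het	Het	-	-	-	Het	-	1320	1820
11	ARMC5	c.508A>G	rs35923277	-	-	-	-	-	-	-	-	Het	-	Het	Het	-	-	-	4147	4510
12	ZNF469	c.1994C>T	rs184583062	-	-	-	-	-	-	-	Het	Het	-	Het	-	-	-	-	783	900
13	KIF1C	c.2105C>T	rs138935423	-	Het	-	Het	Het	-	-	-	-	Het	-	-	-	-	-	752	1280
14	PER1	c.2575C>T	rs112980285	-	-	-	-	-	-	-	Het	-	-	-	Het	-	Het	-	2368	1810
15	PIEZO2	c.4203C>G	rs79261438	Het	-	Het	-	-	-	-	-	-	-	Het	-	-	Het	-	2986	2700
16	HSH2D	c.410C>T	rs36088948	-	-	Het	-	-	-	-	-	Het	-	-	-	Het	Het	-	6876	4430
17	SCAMP4	c.596C>T	rs75734024	-	Het	-	-	-	-	-	-	Het	-	-	-	-	Het	-	1726	1460
18	ZNF568	c.1088C>T	rs1667364	-	-	-	-	-	-	-	-	Het	-	Het	-	-	Het	-	1874	1340
19	CEACAM21	c.253_255dup	rs3030812	-	-	-	-	Het	-	-	-	-	Het	-	-	Het	-	-	4181	3740
20	CEACAM21	c.333C>G	rs78133615	-	-	-	-	Het	-	-	-	-	Het	-	-	Het	-	-	4109	3730
21	PLIN5	c.73C>T	rs11085080	-	-	-	-	-	-	Hom	-	Het	Het	-	-	-	-	-	6443	4910
22	NOP53	c.91G>C	rs78530808	-	-	-	-	Het	-	Het	-	-	-	-	Het	-	-	-	1801	2850
23	NRP2	c.2716_2717insA	rs200483574	-	-	Het	-	Het	-	-	-	-	Het	-	-	-	-	-	4437	4340
24	GCFC2	c.1812+399dup	rs11423284	-	-	Het	Het	-	-	-	-	-	-	Het	-	-	-	-	3960	1638
25	MKKS	c.1015A>G	rs137853909	Het	-	-	-	-	Het	-	-	-	-	Het	-	-	-	-	417	1030
26	CNBD2	c.622A>G	rs6142471	-	-	-	-	Het	-	-	Het	-	Het	-	-	-	-	-	112	749
27	BPI	c.1051C>T	rs5743523	-	-	-	Het	Het	-	Het	-	-	-	Het	-	-	-	-	2502	4070
28	SHANK3	c.2347G>A	rs61729471	-	-	-	-	-	Het	-	-	-	-	-	Het	-	Het	-	3357	4580
29	HCLS1	c.1162G>A	rs77852202	Het	-	-	-	-	Het	-	-	-	Het	-	-	-	-	-	5512	3560
30	DLG1	c.2357G>A	rs78190191	Het	-	Het	-	-	-	-	-	-	-	-	-	-	-	-	2017	3080
31	CCDC149	c.1525C>T	rs74764772	-	Het	-	-	-	-	-	Het	-	-	-	-	Het	-	-	946	2600
32	DNAJC21	c.1024G>A	rs144600070	-	-	-	-	-	Het	-	-	Het	-	-	-	-	-	Het	457	859
33	PHACTR2	c.4G>A	rs41285023	Het	-	-	-	-	-	-	-	-	Het	Het	-	-	-	-	2244	1270
34	TBC1D32	c.3695A>C	rs56300302	Het	-	-	Het	-	-	-	Het	-	-	-	-	-	-	-	1632	1638
35	SCUBE3	c.1229C>T	rs3800381	-	-	-	-	-	-	-	Het	-	-	-	-	Het	-	Het	198	392
36	TSC22D4	c.1150C>T	rs34666277	Het	-	-	-	Hom	-	-	-	-	-	-	-	-	Het	-	626	800
37	CUX1	c.1573C>G	rs138450169	-	Het	-	Het	-	-	-	-	Het	-	-	-	-	-	-	689	1244
38	CRB2	c.278G>A	rs138381817	Het	-	-	-	-	-	-	-	-	-	-	Het	-	-	-	730	896
39	DENND1A	c.2534C>A	rs189947178	Het	Het	-	-	-	-	-	-	-	-	-	Het	-	-	-	679	896
40	TMC1	c.421C>T	rs11143384	-	Het	Het	Hom	-	-	-	-	-	-	-	-	-	-	-	957	990
41	MAN1B1	c.1896+22G>A	rs117994893	Het	-	Het	-	-	-	-	Het	-	-	-	-	-	-	-	3454	4550
42	TXLNG	c.736A>G	rs5969783	-	-	Het	-	Het	-	-	-	-	-	-	-	-	-	Het	2885	2600
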