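sample	PMP	MYS	SureSeq	TSMP	gene	chrom	pos	consequence	transcript	hgvs_c	hgvs_p	classification
1	C	NI	NI	C	GATA2	3	128202767	missense	NM_001145661	c.953C>G	p.Ala318Gly	Pathogenic/COSM249850
2	C	C	C	ND	NRAS	1	115256529	missense	NM_002524	c.182A>G	p.Gln61Arg	Pathogenic/COSM584
2	C	C	C	ND	RUNX1	21	36259151	frameshift	NM_001001890	c.257_258delCC	p.Pro86Hisfs*24	Likely Pathogenic
2	C	C	C	ND	TET2	4	106157572	frameshift	NM_017628	c.2474delC	p.Ser825*fs*1	Likely Pathogenic/COSM4170127
2	C	NI	NI	ND	BCORL1	X	129149890	nonsense	NM_021946	c.3142C>T	p.Arg1048*	Likely Pathogenic
2	C	NI	NI	ND	SH2B3	12	111885286	missense	NM_005475	c.1174C>T	p.Arg392Trp	Likely pathogenic/COSM4384767
3	C	C	C	ND	FLT3	13	28608281	missense	NM_004119	c.1775T>C	p.Val592Ala	Likely Pathogenic/COSM19522
3	C	C	C	ND	NRAS	1	115258744	missense	NM_002524	c.38G>A	p.Gly13Asp	Pathogenic/COSM573
3	C	C	NI	ND	PTPN11	12	112888162	missense	NM_002834	c.178G>T	p.Gly60Cys	Likely Pathogenic
4	C	C	C	ND	CEBPA	19	33792381	inframe_3	NM_004364	c.937_939dupAAG	p.Lys313dup	Likely pathogenic/COSM18397/COSM18099
4	C	NI	NI	ND	GATA2	3	128202767	missense	NM_001145661	c.953C>T	p.Ala318Val	Pathogenic/COSM255084
5	C	C	C	ND	CEBPA	19	33792384	inframe_3	NM_004364	c.934_936dupCAG	p.Gln312dup	Pathogenic/COSM18466
5	C	C	C	ND	CEBPA	19	33793252	frameshift	NM_004364	c.68delC	p.Pro23Argfs*137	Pathogenic/COSM18544
6	C	C	C	ND	CALR	19	13054591	frameshift	NM_004343	c.1119delC	p.Asp373Glufs*?	Likely pathogenic
7	C	C	NC	ND	FLT3	13	28608271	inframe_36	NM_004119	c.1749_1784dup	p.Phe594_Arg595ins12	Pathogenic/ITD
10	C	C	C	ND	TET2	4	106158187	nonsense	NM_017628	c.3088C>T	p.Gln1030*	Likely Pathogenic/COSM4766113
11	C	C	C	ND	FLT3	13	28608255	inframe_21	NM_004119	c.1800_1801ins21	p.Asp600_Leu601ins7	Pathogenic/ITD
11	C	C	C	ND	IDH2	15	90631934	missense	NM_002168	c.419G>A	p.Arg140Gln	Pathogenic/COSM41590
11	C	C	C	ND	NPM1	5	170837543	frameshift	NM_002520	c.860_863dupTCTG	p.Trp288Cysfs*?	Pathogenic/COSM17559/COSM158604
12	C	C	C	ND	FLT3	13	28608273	inframe_33	NM_004119	c.1782_1783ins33	p.Phe594_Arg595ins11	Pathogenic/ITD
12	C	C	C	ND	RUNX1	21	36252865	missense	NM_001001890	c.416G>A	p.Arg139Gln	Likely pathogenic/COSM6908427
13	C	C	C	ND	TET2	4	106157416	nonsense	NM_017628	c.2317G>T	p.Gly773*	Likely pathogenic
13	C	C	NI	ND	SRSF2	17	74732959	missense	NM_001195427	c.284C>A	p.Pro95His	Pathogenic/COSM211504
14	C	C	NC	ND	CALR	19	13054564	frameshift	NM_004343	c.1099_1150del	p.Leu367Thrfs*46	Pathogenic/COSM1738055
15	C	C	C	ND	DNMT3A	2	25470908	nonsense	NM_022552	c.853G>T	p.Glu285*	Likely pathogenic/COSM4383607
15	C	C	C	ND	FLT3	13	28608256	inframe_24	NM_004119	c.1799_1800ins24	p.Asp600_Leu601ins8	Pathogenic/ITD
15	C	C	NI	ND	SF3B1	2	198267359	missense	NM_012433	c.1998G>T	p.Lys666Asn	Pathogenic/COSM131557
16	C	ND	NC	ND	FLT3	13	28608286	inframe_36	NM_004119	c.1734_1769dup	p.Tyr589_Phe590ins12	Pathogenic/ITD
16	C	ND	C	ND	WT1	11	32417924	frameshift	NM_000378	c.1076_1077insT	p.Thr360Aspfs*8	Likely pathogenic
17	C	ND	ND	C	U2AF1	21	44514777	missense	NM_001025203	c.470A>C	p.Gln157Pro	Pathogenic/COSM211534
18	C	ND	ND	C	NRAS	1	115258747	missense	NM_002524	c.35G>A	p.Gly12Asp	Pathogenic/COSM564
18	C	ND	ND	C	SRSF2	17	74732960	missense	NM_001195427	c.283C>A	p.Pro95Thr	Pathogenic/COSM307353
18	C	ND	ND	C	WT1	11	32417911	frameshift	NM_000378	c.1089_1090insGCCCTCTTGTACGG	p.Ser364Alafs*73	Likely pathogenic
20	NI	ND	ND	C	GNAS	20	57484421	missense	NM_080425.2	c.2531G>A	p.Arg844His	Likely pathogenic/COSM94388
20	C	ND	ND	C	ASXL1	20	31024704	missense	NM_015338	c.4189G>A	p.Gly1397Ser	Pathogenic/COSM133033
20	C	ND	ND	C	SF3B1	2	198267484	missense	NM_012433	c.1873C>T	p.Arg625Cys	Pathogenic/COSM110696
21	C	ND	ND	C	CALR	19	13054564	frameshift	NM_004343	c.1099_1150del	p.Leu367Thrfs*46	Pathogenic/COSM1738055
23	C	ND	ND	C	MPL	1	43815009	missense	NM_005373	c.1544G>T	p.Trp515Leu	Pathogenic/COSM3719407,COSM18918
24	C	ND	ND	C	SETBP1	18	42531913	missense	NM_015559	c.2608G>C	p.Gly870Arg	Pathogenic/COSM1684722
25	C	ND	ND	C	ASXL1	20	31022288	nonsense	NM_015338	c.1773C>A	p.Tyr591*	Pathogenic/COSM1681609
25	C	ND	ND	C	KIT	4	55599321	missense	NM_000222	c.2447A>T	p.Asp816Val	Pathogenic/COSM1314
26	C	ND	ND	C	GATA1	X	48649629	missense	NM_002049	c.113C>T	p.Pro38Leu	Likely Pathogenic/COSM6498484,COSM6498483
27	C	ND	ND	C	CALR	19	13054627	frameshift	NM_004343	c.1154_1155insTTGTC	p.Lys385Asnfs*	Pathogenic/COSM1738056
27	C	ND	ND	C	U2AF1	21	44514777	missense	NM_001025203	c.470A>G	p.Gln157Arg	Pathogenic/COSM211532,COSM1724986
28	C	ND	ND	C	ASXL1	20	31022441	frameshift	NM_015338	c.1934dupG	p.Gly646fs*12	Pathogenic/COSM34210
28	C	ND	ND	C	TP53	17	7577094	missense	NM_000546	c.844C>T	p.Arg282Trp	Pathogenic/COSM99925,COSM1636702,COSM10704
31	C	ND	ND	C	FLT3	13	28608244	inframe_24	NM_004119	c.1788_1811dup	p.Glu604_Phe605ins8	Pathogenic/ITD
31	C	ND	ND	C	WT1	11	32417907	frameshift	NM_000378	c.1090_1093dupTCGG	p.Ala382ValfsTer4	Pathogenic/COSM5487332
32	C	ND	ND	C	CBL	11	119148931	missense	NM_005188	c.1151G>A	p.Cys384Tyr	Pathogenic/COSM34066
32	C	ND	ND	C	WT1	11	32417913	frameshift	NM_000378	c.1080_1087dupTCTTGTAC	p.Arg380LeufsTer72	Likely Pathogenic/COSM5487152
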