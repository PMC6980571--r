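# Partial, reduced transcription of the panel's target design:
# one synthetic span per targeted gene (plus named exon detail for MPL/ASXL1).
# Spans are synthetic; the full per-exon tilings are not published.
1	36931000	36934000	CSF3R	target
1	43814500	43815300	MPL	exon 10
1	115250000	115260000	NRAS	target
10	89623000	89626000	PTEN	target
10	112327000	112330000	SMC3	target
11	532000	535000	HRAS	target
11	32410000	32420000	WT1	target
11	118307000	118310000	KMT2A	target
11	119145000	119150000	CBL	target
12	11905000	11910000	ETV6	target
12	25378000	25380000	KRAS	target
12	112884000	112895000	PTPN11	target
13	28605000	28611000	FLT3	target
15	90627000	90634000	IDH2	target
17	7572000	7580000	TP53	target
17	74730000	74734000	SRSF2	target
18	42528000	42533000	SETBP1	target
19	13049000	13056000	CALR	target
19	33792244	33793321	CEBPA	CDS
2	25455000	25475000	DNMT3A	target
2	198265000	198270000	SF3B1	target
2	209113000	209116000	IDH1	target
20	31020000	31025000	ASXL1	target
20	57480000	57486000	GNAS	target
21	36250000	36262000	RUNX1	target
21	44510000	44520000	U2AF1	target
3	38179000	38182000	MYD88	target
3	128198000	128208000	GATA2	target
4	55595000	55600000	KIT	target
4	106155000	106165000	TET2	target
4	153242000	153245000	FBXW7	target
5	170834000	170838000	NPM1	target
7	50444000	50446000	IKZF1	target
7	101459000	101462000	CUX1	target
7	140433000	140436000	BRAF	target
7	148504000	148509000	EZH2	target
8	117858000	117861000	RAD21	target
9	5069000	5074000	JAK2	target
9	21967000	21970000	CDKN2A	target
9	133589000	133592000	ABL1	target
9	139388000	139391000	NOTCH1	target
X	15808000	15812000	ZRSR2	target
X	39921000	39924000	BCOR	target
X	48645000	48652000	GATA1	target
X	53401000	53404000	SMC1A	target
X	76760000	76764000	ATRX	target
X	123156000	123159000	STAG2	target
X	129145000	129155000	BCORL1	target
X	133511000	133513000	PHF6	target
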