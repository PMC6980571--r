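# Partial, reduced transcription of the panel's target design:
# one synthetic span per targeted gene (plus named exon detail for MPL/ASXL1).
# Spans are synthetic; the full per-exon tilings are not published.
1	43814500	43815300	MPL	exon 10
1	115250000	115260000	NRAS	target
11	32410000	32420000	WT1	target
11	118307000	118310000	KMT2A	target
12	11905000	11910000	ETV6	target
12	25378000	25380000	KRAS	target
13	28605000	28611000	FLT3	target
15	90627000	90634000	IDH2	target
17	7572000	7580000	TP53	target
19	13049000	13056000	CALR	target
19	33792244	33793321	CEBPA	CDS
2	25455000	25475000	DNMT3A	target
2	209113000	209116000	IDH1	target
20	30946000	31025000	ASXL1	CDS
21	36250000	36262000	RUNX1	target
21	44510000	44520000	U2AF1	target
4	55595000	55600000	KIT	target
4	106155000	106165000	TET2	target
5	170834000	170838000	NPM1	target
9	5069000	5074000	JAK2	target
X	39921000	39924000	BCOR	target
X	48645000	48652000	GATA1	target
X	133511000	133513000	PHF6	target
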