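sample	diagnosis	panels
1	AML	PMP,MYS,SureSeq,TSMP
2	AML	PMP,MYS,SureSeq
3	AML	PMP,MYS,SureSeq
4	AML	PMP,MYS,SureSeq
5	AML	PMP,MYS,SureSeq
6	MPN	PMP,MYS,SureSeq
7	AML	PMP,MYS,SureSeq
8	AML	PMP,MYS,SureSeq
9	AML	PMP,MYS,SureSeq
10	AML	PMP,MYS,SureSeq
11	AML	PMP,MYS,SureSeq
12	AML	PMP,MYS,SureSeq
13	AML	PMP,MYS,SureSeq
14	MPN	PMP,MYS,SureSeq
15	AML	PMP,MYS,SureSeq
16	AML	PMP,SureSeq
17	MDS	PMP,TSMP
18	AML	PMP,TSMP
19	MDS	PMP,TSMP
20	MDS	PMP,TSMP
21	MPN	PMP,TSMP
22	MPN	PMP,TSMP
23	MPN	PMP,TSMP
24	CMML	PMP,TSMP
25	MDS	PMP,TSMP
26	MPN	PMP,TSMP
27	MPN	PMP,TSMP
28	MDS	PMP,TSMP
29	AML	PMP,TSMP
30	AML	PMP,TSMP
31	MDS	PMP,TSMP
32	CMML	PMP,TSMP
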