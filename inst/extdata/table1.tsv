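sample	pathology	diagnosis	karyotype	fish	molecular	cebpa_status	flt3_itd_ratio	flt3_itd_class	npm1_status	calr_status	jak2_status	mpl_status
1	AML	AML	46, XY	NP	CEBPA biallelic	biallelic	NA	not_tested	not_tested	not_tested	not_tested	not_tested
2	AML secondary to MDS	AML	46,XX, del(20)(q12)/46,XX	NP	FLT3-ITD favorable/NPM1 non mutated	not_tested	NA	favorable	not_mutated	not_tested	not_tested	not_tested
3	AML secondary to treatment	AML	46,XX del(11)t(11;11)(p15;q23)/46,XX	11q23 (KMT2A/MLL) negative	FLT3-ITD favorable/NPM1 non mutated	not_tested	NA	favorable	not_mutated	not_tested	not_tested	not_tested
4	AML	AML	NA	RUNX1-RUNXT1 negative	CEBPA monoallelic	monoallelic	NA	not_tested	not_tested	not_tested	not_tested	not_tested
5	AML M1	AML	NP	PDGFRb, FGFR1 negative	CEBPA biallelic	biallelic	NA	not_tested	not_tested	not_tested	not_tested	not_tested
6	Essential Thrombocytopenia	MPN	NP	NP	CALR	not_tested	NA	not_tested	not_tested	mutated	not_tested	not_tested
7	AML M5	AML	NP	NP	FLT3-ITD favorable/NPM1 non mutated/WT1 overexpressed	not_tested	NA	favorable	not_mutated	not_tested	not_tested	not_tested
8	AML	AML	NP	NP	CEBPA biallelic	biallelic	NA	not_tested	not_tested	not_tested	not_tested	not_tested
9	AML M1	AML	NP	PDGFRb negative	CEBPA monoallelic/FLT3 non mutated	monoallelic	NA	not_mutated	not_tested	not_tested	not_tested	not_tested
10	AML	AML	46, XY	NP	CEBPA monoallelic	monoallelic	NA	not_tested	not_tested	not_tested	not_tested	not_tested
11	AML M1	AML	NP	NP	FLT3-ITD favorable/NPM1 mutated	not_tested	NA	favorable	mutated	not_tested	not_tested	not_tested
12	AML	AML	NP	NP	FLT3-ITD favorable/CEBPA and NPM1 non mutated	not_mutated	NA	favorable	not_mutated	not_tested	not_tested	not_tested
13	AML	AML	46, XX	NP	CEBPA monoallelic	monoallelic	NA	not_tested	not_tested	not_tested	not_tested	not_tested
14	Essential Thrombocytopenia	MPN	NP	NP	CALR mutated/JAK2 non mutated	not_tested	NA	not_tested	not_tested	mutated	not_mutated	not_tested
15	AML secondary CMML	AML	NA	NP	FLT3-ITD (ratio 1,11) Unfavorable	not_tested	1,11	unfavorable	not_tested	not_tested	not_tested	not_tested
16	AML	AML	46, XY	NP	FLT3-ITD (ratio 1,06) Unfavorable	not_tested	1,06	unfavorable	not_tested	not_tested	not_tested	not_tested
17	MDS	MDS	45,X,-Y/46,XY	del(5q) and del(7q) negative	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
18	AML M2	AML	NP	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
19	MDS	MDS	47,XY,+13/46,XY	del(5q), del(20q) and del(7q) negative	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
20	MDS-EB1	MDS	46,XX	del(5q), del(20q) and del(7q) negative	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
21	Myelofibrosis	MPN	NP	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
22	Myelofibrosis	MPN	NP	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
23	Myelofibrosis	MPN	NA	NP	MPN Triple Negative	not_tested	NA	not_tested	not_tested	not_mutated	not_mutated	not_mutated
24	CMML	CMML	46,XX	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
25	MDS	MDS	46,XX	del(5q), del(20q) and del(7q) negative	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
26	Polycythemia Vera	MPN	NP	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
27	Myelofibrosis	MPN	NP	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
28	MDS (del(5q))	MDS	NP	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
29	AML	AML	NP	NP	FLT3 (ITD-D835) non mutated/CEBPA and NPM1 non mutated	not_mutated	NA	not_mutated	not_mutated	not_tested	not_tested	not_tested
30	AML in treatment	AML	46,XY,t(3;6)(q26;q21)	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
31	MDS-EB2	MDS	46,XY,inv(9)(p12q13)	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
32	CMML	CMML	46,XY,add(15)(p13),add(21)(q22)	NP	NP	not_tested	NA	not_tested	not_tested	not_tested	not_tested	not_tested
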