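# Partial gene-level clinical-relevance annotation for the genes named in the
# study text; evidence and disease flags are comma-separated subsets of
# {diagnostic,prognostic,predictive,predisposition} and {AML,MDS,MPN,CMML,lymphoid}.
gene	relevance	evidence	diseases
ASXL1	clinically_relevant	prognostic	AML,MDS,CMML
CALR	clinically_relevant	diagnostic,prognostic,predictive	MPN
CEBPA	clinically_relevant	prognostic	AML
DNMT3A	clinically_relevant	prognostic,predictive	AML,MDS
ETV6	clinically_relevant	prognostic	AML,MDS
FLT3	clinically_relevant	prognostic,predictive	AML
IDH1	clinically_relevant	prognostic,predictive	AML,MDS
IDH2	clinically_relevant	prognostic,predictive	AML,MDS
JAK2	clinically_relevant	diagnostic,prognostic,predictive	MPN
KIT	clinically_relevant	prognostic,predictive	AML
KRAS	clinically_relevant	prognostic	AML,CMML
MPL	clinically_relevant	diagnostic,prognostic	MPN
NPM1	clinically_relevant	prognostic	AML
NRAS	clinically_relevant	prognostic	AML,CMML
RUNX1	clinically_relevant	prognostic	AML,MDS
TET2	clinically_relevant	prognostic,predictive	AML,MDS,CMML
TP53	clinically_relevant	prognostic	AML,MDS
U2AF1	clinically_relevant	prognostic	MDS
WT1	clinically_relevant	prognostic	AML
SF3B1	clinically_relevant	diagnostic,prognostic	MDS
SRSF2	clinically_relevant	prognostic	MDS,CMML
ZRSR2	clinically_relevant	prognostic	MDS
EZH2	clinically_relevant	prognostic	MDS,CMML
CBL	clinically_relevant	prognostic	MDS,CMML
CSF3R	clinically_relevant	diagnostic,prognostic	MPN
SETBP1	clinically_relevant	prognostic	MDS,CMML
PTPN11	clinically_relevant	prognostic	AML,MDS
GATA2	clinically_relevant	prognostic,predisposition	AML,MDS
IKZF1	clinically_relevant	prognostic	AML,MDS
PHF6	clinically_relevant	prognostic	AML,MDS
BCOR	clinically_relevant	prognostic	AML,MDS
GATA1	clinically_relevant	prognostic	AML,MDS
KMT2A	clinically_relevant	prognostic	AML
SH2B3	clinically_relevant	prognostic	MPN
NF1	clinically_relevant	prognostic	AML,MDS
PPM1D	clinically_relevant	prognostic	MDS
CSNK1A1	clinically_relevant	prognostic	MDS
ANKRD26	clinically_relevant	predisposition	AML,MDS
DDX41	clinically_relevant	predisposition	AML,MDS
SRP72	clinically_relevant	predisposition	AML,MDS
ABL1	clinically_relevant	diagnostic,predictive	AML
MYD88	not_relevant		lymphoid
NOTCH1	not_relevant		lymphoid
PTEN	not_relevant		lymphoid
CDKN2A	not_relevant		lymphoid
FBXW7	not_relevant		lymphoid
BRAF	unknown
HRAS	unknown
GNAS	unknown
ATRX	unknown
BCORL1	unknown
CUX1	unknown
RAD21	unknown
SMC1A	unknown
SMC3	unknown
STAG2	unknown
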