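ASXL1
CALR
CEBPA
DNMT3A
ETV6
FLT3
IDH1
IDH2
JAK2
KIT
KRAS
MPL
NPM1
NRAS
RUNX1
TET2
TP53
U2AF1
WT1
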