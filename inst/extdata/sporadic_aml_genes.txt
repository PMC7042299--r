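# genes reported mutated in sporadic AML (TCGA-LAML / BeatAML)
FLT3
NPM1
DNMT3A
IDH1
IDH2
TET2
RUNX1
TP53
NRAS
KRAS
CEBPA
WT1
PTPN11
KIT
U2AF1
SMC1A
SMC3
RAD21
STAG2
PHF6
ASXL1
EZH2
SRSF2
SF3B1
ZRSR2
BCOR
GATA2
JAK2
CALR
MPL
CSF3R
SETBP1
ETV6
IKZF1
GNAS
MYC
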