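gene
TP53
CDKN2A
PIK3CA
NOTCH1
FAT1
EGFR
CCND1
HRAS
CASP8
NSD1
TP63
FBXW7
KMT2D
AJUBA
PTEN
RB1
NFE2L2
CUL3
KEAP1
FGFR1
MYC
SOX2
TRAF3
HLA-A
B2M
STAT3
AKT1
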