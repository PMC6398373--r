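gene_a	gene_b	type
AJUBA	RB1	interaction
BAG3	FAT1	interaction
BAG3	SOX2	interaction
BAG3	TP53	interaction
CCND1	TRAF3	interaction
CDKN2A	MYC	interaction
CITED2	FBXW7	interaction
CITED2	RB1	interaction
CITED2	STAT3	interaction
DDIT3	HLA-A	interaction
DDIT3	NFE2L2	interaction
DDIT3	RGS16	interaction
DDIT4	TP63	interaction
DNAJB1	RB1	interaction
DUSP1	CASP8	interaction
DUSP1	EMP1	interaction
DUSP1	TP63	interaction
EMP1	HSPA1L	interaction
EMP1	TP63	interaction
FAT1	FBXW7	interaction
FBXW7	AJUBA	interaction
GADD45B	B2M	interaction
GADD45B	DDIT3	interaction
GADD45B	DEDD2	interaction
GADD45B	EMP1	interaction
GADD45B	HSPA1L	interaction
GADD45B	KEAP1	interaction
HBEGF	DNAJB1	interaction
HBEGF	NFE2L2	interaction
HMOX1	CASP8	interaction
HMOX1	FAT1	interaction
HSPA1A	SOX2	interaction
HSPA1L	DEDD2	interaction
HSPA1L	TP63	interaction
HSPB8	CASP8	interaction
HSPB8	PIK3CA	interaction
HSPB8	SOX2	interaction
HSPB8	TP63	interaction
KMT2D	AJUBA	interaction
KMT2D	AKT1	interaction
LRRC15	TP63	interaction
MIR21	EGFR	interaction
MIR21	TP53	interaction
NOTCH1	AKT1	interaction
NOTCH1	TRAF3	interaction
NSD1	B2M	interaction
PIK3CA	STAT3	interaction
PIM1	VDR	interaction
PTEN	TRAF3	interaction
PTGS2	BAG3	interaction
PTGS2	CASP8	interaction
PTGS2	DDIT3	interaction
RB1	STAT3	interaction
RGS16	CASP8	interaction
RGS16	FBXW7	interaction
RGS16	PTEN	interaction
RGS16	STAT3	interaction
RPA1	HRAS	interaction
RPA2	FAT1	interaction
RPA2	HRAS	interaction
RPA2	TRAF3	interaction
SPHK1	NSD1	interaction
SPHK1	RGS16	interaction
SPHK1	VDR	interaction
TGIF1	HRAS	interaction
TGIF1	SOX2	interaction
TIMP3	AKT1	interaction
VDR	BAG3	interaction
VDR	FAT1	interaction
VDR	NOTCH1	interaction
VDR	RPA2	interaction
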