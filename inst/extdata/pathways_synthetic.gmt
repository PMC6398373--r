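TGFB_SIGNALING	synthetic TGF-beta signaling response set	LRRC15	CITED2	RHOB	TIMP3	GADD45B	TGIF1	PIM1	SPHK1	PTGS2	DDIT3	DUSP1	DDIT4	MIR21	RGS16	HMOX1	HBEGF	EMP1	VDR	GABARAPL1	SMAD2	SMAD3	SMAD4	TGFB1	TGFBR1	TGFBR2	SKIL	SERPINE1	JUNB	ID1
HSF1_ACTIVATION	synthetic HSF-1 activation set	DNAJB1	HSPA1L	HSPA1A	DEDD2	RPA1	RPA2	BAG3	PLK1	SPHK1	HSF1	HSPA8	HSPA4
HSF1_DEPENDENT_TRANSACTIVATION	synthetic HSF-1-dependent transactivation set	DNAJB1	HSPA1L	HSPA1A	DEDD2	HSPB8	HSF1	HSPH1	DNAJA1
ATTENUATION_PHASE	synthetic heat-shock attenuation phase set	DNAJB1	HSPA1A	DEDD2	HSPB8	HSF1
MAPK_PI3K_SIGNALING	synthetic MAPK/PI3K signaling set	MAPK1	MAPK3	MAP2K1	PIK3CA	PIK3R1	AKT1	AKT2	RAF1	BRAF	KRAS	HRAS	EGFR	DUSP1	HBEGF	GADD45B
CELL_CYCLE	synthetic cell-cycle decoy set	CCND1	CCNE1	CDK2	CDK4	CDK6	RB1	E2F1	CDKN1A	CDKN2A	PLK1	BUB1	AURKA
APOPTOSIS	synthetic apoptosis decoy set	CASP3	CASP8	CASP9	BAX	BAK1	BCL2	BCL2L1	BID	FAS	FADD	APAF1	TP53
ECM_RECEPTOR_INTERACTION	synthetic ECM-receptor interaction decoy set	COL1A1	COL4A1	FN1	LAMA1	LAMB1	ITGA1	ITGB1	SDC1	CD44	THBS1
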