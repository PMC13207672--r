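Activated_CD8_T_cell	synthetic immune signature	CD8A	CD8B	GZMA	GZMB	PRF1	IFNG	KLRG1	CX3CR1
Central_memory_CD8_T_cell	synthetic immune signature	CD8A	CCR7	SELL	IL7R	TCF7	BCL2	CD27	CD28
Effector_memory_CD8_T_cell	synthetic immune signature	CD8A	GZMK	KLRD1	EOMES	CXCR3	CD44	FASLG	TBX21
Activated_CD4_T_cell	synthetic immune signature	CD4	IL2RA	CD69	ICOS	CD40LG	IL2	TNF	CD38
Central_memory_CD4_T_cell	synthetic immune signature	CD4	CCR7	SELL	IL7R	TCF7	CD27	CD28	LEF1
Effector_memory_CD4_T_cell	synthetic immune signature	CD4	GZMK	CCL5	CXCR3	PRDM1	IL2RB	KLRB1	CD58
T_follicular_helper_cell	synthetic immune signature	CXCR5	BCL6	ICOS	PDCD1	IL21	CD200	SH2D1A	BTLA
Gamma_delta_T_cell	synthetic immune signature	TRGC1	TRDC	KLRC1	NKG7	GNLY	CD160	KLRK1	IL17A
Type_1_T_helper_cell	synthetic immune signature	TBX21	IFNG	IL12RB2	STAT4	CXCR3	CCR5	IL18R1	HAVCR2
Type_2_T_helper_cell	synthetic immune signature	GATA3	IL4	IL5	IL13	CCR4	PTGDR2	STAT6	IL17RB
Type_17_T_helper_cell	synthetic immune signature	RORC	IL17A	IL17F	IL22	CCR6	IL23R	STAT3	AHR
Regulatory_T_cell	synthetic immune signature	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18	CCR8	TIGIT	LAG3
Activated_B_cell	synthetic immune signature	CD19	MS4A1	CD79A	CD79B	CD86	TNFRSF13B	IGHM	CD69
Immature_B_cell	synthetic immune signature	CD19	MS4A1	CD38	IGHD	CD24	CR2	FCER2	BACH2
Memory_B_cell	synthetic immune signature	CD19	MS4A1	CD27	TNFRSF13B	AIM2	SCIMP	CD80	SPIB
Natural_killer_cell	synthetic immune signature	NCAM1	KLRD1	KLRF1	NKG7	GNLY	NCR1	KIR2DL3	PRF1
MDSC	synthetic immune signature	ITGAM	CD33	ARG1	NOS2	S100A8	S100A9	IL4R	STAT3
Macrophage	synthetic immune signature	CD68	CD163	MRC1	CSF1R	MSR1	MARCO	LYZ	ITGAX
Activated_dendritic_cell	synthetic immune signature	CD83	CD80	CD86	CCR7	LAMP3	IDO1	CD40	RELB
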