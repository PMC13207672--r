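NFE2L2	synthetic NRF2 regulon	HMOX1	NQO1	GCLC	GCLM	TXNRD1	GSS	SLC7A11	FTH1	FTL	GPX4	PRDX1	SESN2
AR	synthetic androgen receptor regulon	KLK3	KLK2	TMPRSS2	NKX3-1	FKBP5	PMEPA1	NDRG1	MAF	ZBTB16	ABCC4
FOXA1	synthetic FOXA1 regulon	KLK3	TMPRSS2	NKX3-1	CDH1	ESR1	GATA3	TFF1	SPDEF	AGR2	FOXP1
TP53	synthetic p53 regulon	CDKN1A	MDM2	BAX	BBC3	GADD45A	SFN	TP53I3	SESN1	SESN2	GLS2	SAT1	PTGS2
HIF1A	synthetic HIF1A regulon	VEGFA	SLC2A1	CA9	LDHA	PGK1	EPO	BNIP3	PDK1	HK2	ENO1
ATF4	synthetic ATF4 regulon	CHAC1	DDIT3	TRIB3	ASNS	PSAT1	PHGDH	SLC7A11	ATF3	PPP1R15A	VEGFA
BACH1	synthetic BACH1 regulon	HMOX1	FTH1	FTL	SLC40A1	ME1	GCLM	TXNRD1	SLC7A11	NQO1	PRDX1
STAT3	synthetic STAT3 regulon	SOCS3	BCL3	MYC	CCND1	VEGFA	MMP9	IL6	JUNB	PIM1	BCL2L1
MYC	synthetic MYC regulon	CDK4	CCND2	NPM1	NCL	ODC1	LDHA	RPL8	EIF4E	SLC1A5	GLS2
SP1	synthetic SP1 regulon	VEGFA	TGFB1	CDKN1A	FASN	LDLR	TFRC	COL1A1	MMP2	TERT	SOD1
JUN	synthetic JUN regulon	MMP1	CCND1	VIM	FOSL1	PLAU	PLAUR	HBEGF	TRIB1	ETS2	MAFF
FOS	synthetic FOS regulon	MMP1	MMP3	CCND1	VIM	CXCL8	TIMP1	KRT18	HSPB1
EGR1	synthetic EGR1 regulon	PDGFA	TGFB1	PTEN	FN1	SERPINE1	TP53	CDKN1A	EGR2
KLF4	synthetic KLF4 regulon	CDKN1A	CDH1	KRT4	KRT13	OCLN	TFF3	VILL	SPRR1A
SREBF1	synthetic SREBF1 regulon	FASN	SCD	ACACA	LDLR	HMGCR	ELOVL6	ACLY	MVD
PPARG	synthetic PPARG regulon	CD36	FABP4	LPL	ADIPOQ	PLIN1	ACOX1	SCD	UCP1
STAT1	synthetic STAT1 regulon	IRF1	GBP1	CXCL9	CXCL10	ISG15	OAS1	MX1	PSMB9
IRF1	synthetic IRF1 regulon	GBP1	CXCL10	PSMB9	TAP1	IL15	CASP1	IFIT3	SOCS1
E2F1	synthetic E2F1 regulon	CCNE1	CDC6	MCM2	MCM3	PCNA	RRM2	TYMS	DHFR
FOXO3	synthetic FOXO3 regulon	SOD2	CAT	GADD45A	BNIP3	CDKN1B	BCL2L11	SESN3	TXNIP
CEBPB	synthetic CEBPB regulon	IL6	IL1B	SAA1	CRP	SOCS3	ARG1	PTX3	MYD88
YAP1	synthetic YAP1 regulon	CCN2	CCN1	ANKRD1	AMOTL2	THBS1	AXL	BIRC5	GLI2
SMAD3	synthetic SMAD3 regulon	SERPINE1	COL1A1	CCN2	JUNB	SMAD7	SKIL	TGFBI	TIMP1
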