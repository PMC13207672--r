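iron_metabolism	synthetic reconstruction of the iron handling axis	TFRC	FTH1	FTL	SLC40A1	STEAP3	NCOA4	HMOX1	SLC11A2	TF	CP	HEPH	ISCU	CISD1	CISD2	FXN	ACO1
lipid_peroxidation	synthetic reconstruction of the lipid peroxidation axis	ACSL4	LPCAT3	ALOX15	ALOX5	ALOX12	ALOXE3	PTGS2	POR	FASN	ELOVL5	FADS2	SCD	ACSL3	PEBP1	AKR1C1	AKR1C2
antioxidant_defense	synthetic reconstruction of the antioxidant defense axis	NFE2L2	KEAP1	NQO1	TXNRD1	GCLC	GCLM	AIFM2	DHODH	NOX4	NOX1	CBS	GDF15	MT1G	AKR1C3	ALDH3A2	CHAC1	SESN2	PRDX1
gpx4_axis	synthetic reconstruction of the system Xc-/GSH/GPX4 axis	GPX4	SLC7A11	SLC3A2	GSS	GSR	GLS2	CTH	SLC1A5	GOT1	CARS1	CD44	ATF4
ferroptosis_all	synthetic 80-gene ferroptosis union	TFRC	FTH1	FTL	SLC40A1	STEAP3	NCOA4	HMOX1	SLC11A2	TF	CP	HEPH	ISCU	CISD1	CISD2	FXN	ACO1	ACSL4	LPCAT3	ALOX15	ALOX5	ALOX12	ALOXE3	PTGS2	POR	FASN	ELOVL5	FADS2	SCD	ACSL3	PEBP1	AKR1C1	AKR1C2	NFE2L2	KEAP1	NQO1	TXNRD1	GCLC	GCLM	AIFM2	DHODH	NOX4	NOX1	CBS	GDF15	MT1G	AKR1C3	ALDH3A2	CHAC1	SESN2	PRDX1	GPX4	SLC7A11	SLC3A2	GSS	GSR	GLS2	CTH	SLC1A5	GOT1	CARS1	CD44	ATF4	ZEB1	CDKN2A	HSPB1	SAT1	DPP4	FANCD2	HELLS	TFAP2C	EMC2	CRYAB	RPL8	ATG5	ATG7	MAP1LC3B	VDAC2	VDAC3	NFS1	PANX1
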