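source	target
Acta2	ACTA2
Actb	ACTB
Adgre1	ADGRE1
Aif1	AIF1
Aim2	AIM2
Alox15	ALOX15
Alox5	ALOX5
Angpt1	ANGPT1
Angpt2	ANGPT2
Anxa1	ANXA1
Anxa2	ANXA2
Arg1	ARG1
B2m	B2M
Batf	BATF
Batf3	BATF3
Bcl2	BCL2
Bcl6	BCL6
Bhlhe40	BHLHE40
Blnk	BLNK
Bst2	BST2
Btk	BTK
Btla	BTLA
Cadm1	CADM1
Camp	CAMP
Card11	CARD11
Casp1	CASP1
Casp4	CASP4
Ccl1	CCL1
Ccl11	CCL11
Ccl12	CCL12
Ccl17	CCL17
Ccl19	CCL19
Ccl2	CCL2
Ccl20	CCL20
Ccl21	CCL21
Ccl22	CCL22
Ccl24	CCL24
Ccl25	CCL25
Ccl27	CCL27
Ccl28	CCL28
Ccl3	CCL3
Ccl4	CCL4
Ccl5	CCL5
Ccl6	CCL6
Ccl7	CCL7
Ccl8	CCL8
Ccl9	CCL9
Ccr1	CCR1
Ccr10	CCR10
Ccr2	CCR2
Ccr3	CCR3
Ccr4	CCR4
Ccr5	CCR5
Ccr6	CCR6
Ccr7	CCR7
Ccr8	CCR8
Ccr9	CCR9
Cd14	CD14
Cd160	CD160
Cd163	CD163
Cd19	CD19
Cd1d1	CD1D1
Cd2	CD2
Cd200	CD200
Cd200r1	CD200R1
Cd22	CD22
Cd24	CD24
Cd244a	CD244
Cd27	CD27
Cd28	CD28
Cd3	CD3
Cd33	CD33
Cd34	CD34
Cd36	CD36
Cd37	CD37
Cd38	CD38
Cd3d	CD3D
Cd3e	CD3E
Cd3g	CD3G
Cd4	CD4
Cd40	CD40
Cd44	CD44
Cd47	CD47
Cd48	CD48
Cd5	CD5
Cd52	CD52
Cd53	CD53
Cd55	CD55
Cd58	CD58
Cd6	CD6
Cd63	CD63
Cd68	CD68
Cd69	CD69
Cd7	CD7
Cd72	CD72
Cd74	CD74
Cd79a	CD79A
Cd79b	CD79B
Cd8	CD8
Cd80	CD80
Cd81	CD81
Cd83	CD83
Cd86	CD86
Cd8a	CD8A
Cd8b1	CD8B
Cd9	CD9
Cd93	CD93
Cd96	CD96
Cd97	CD97
Cdh5	CDH5
Cebpa	CEBPA
Cebpb	CEBPB
Ciita	CIITA
Cish	CISH
Cldn5	CLDN5
Clec9a	CLEC9A
Cma1	CMA1
Col14a1	COL14A1
Col15a1	COL15A1
Col1a1	COL1A1
Col1a2	COL1A2
Col3a1	COL3A1
Col4a1	COL4A1
Col4a2	COL4A2
Col5a1	COL5A1
Col5a2	COL5A2
Col6a1	COL6A1
Col6a2	COL6A2
Col6a3	COL6A3
Cpa3	CPA3
Csf1	CSF1
Csf1r	CSF1R
Csf2	CSF2
Csf2ra	CSF2RA
Csf2rb	CSF2RB
Csf3	CSF3
Csf3r	CSF3R
Ctla4	CTLA4
Ctnnb1	CTNNB1
Ctsg	CTSG
Cx3cr1	CX3CR1
Cxcl1	CXCL1
Cxcl10	CXCL10
Cxcl11	CXCL11
Cxcl12	CXCL12
Cxcl13	CXCL13
Cxcl14	CXCL14
Cxcl15	CXCL15
Cxcl16	CXCL16
Cxcl17	CXCL17
Cxcl2	CXCL2
Cxcl3	CXCL3
Cxcl4	CXCL4
Cxcl5	CXCL5
Cxcl9	CXCL9
Cxcr1	CXCR1
Cxcr2	CXCR2
Cxcr3	CXCR3
Cxcr4	CXCR4
Cxcr5	CXCR5
Cxcr6	CXCR6
Dcn	DCN
Ddx58	DDX58
Dll1	DLL1
Dll4	DLL4
Dntt	DNTT
Ear2	EAR2
Ebf1	EBF1
Egr1	EGR1
Elane	ELANE
Eng	ENG
Eomes	EOMES
Epas1	EPAS1
Epx	EPX
Esam	ESAM
Fap	FAP
Fbln1	FBLN1
Fbln2	FBLN2
Fcer1a	FCER1A
Fcer1g	FCER1G
Fcer2a	FCER2
Fcgr1	FCGR1
Fcgr2	FCGR2
Fcgr3	FCGR3
Fcgr4	FCGR3A
Fcgrt	FCGRT
Fcrls	FCRLS
Flt1	FLT1
Flt3	FLT3
Flt3l	FLT3L
Fn1	FN1
Fos	FOS
Foxp3	FOXP3
Gapdh	GAPDH
Gata1	GATA1
Gata3	GATA3
Gpr34	GPR34
Gsdmd	GSDMD
Gypa	GYPA
Gzma	GZMA
Gzmb	GZMB
Gzmk	GZMK
Gzmm	GZMM
H2-Aa	HLA-DQA1
H2-Ab1	HLA-DQB1
H2-Eb1	HLA-DRB1
Havcr2	HAVCR2
Hba-a1	HBA1
Hbb-bs	HBB
Hdc	HDC
Hes1	HES1
Hexb	HEXB
Hey1	HEY1
Hif1a	HIF1A
Hmox1	HMOX1
Hprt	HPRT
Icam1	ICAM1
Icos	ICOS
Id2	ID2
Id3	ID3
Ifih1	IFIH1
Ifit1	IFIT1
Ifit3	IFIT3
Ifnar1	IFNAR1
Ifnar2	IFNAR2
Ifng	IFNG
Ifngr1	IFNGR1
Ifngr2	IFNGR2
Ighm	IGHM
Igll1	IGLL1
Ikzf1	IKZF1
Ikzf2	IKZF2
Ikzf3	IKZF3
Il10	IL10
Il10ra	IL10RA
Il11	IL11
Il12	IL12
Il12rb1	IL12RB1
Il13	IL13
Il13ra1	IL13RA1
Il15	IL15
Il15ra	IL15RA
Il16	IL16
Il17	IL17
Il17ra	IL17RA
Il18	IL18
Il1a	IL1A
Il1b	IL1B
Il1r1	IL1R1
Il2	IL2
Il21	IL21
Il21r	IL21R
Il22	IL22
Il23	IL23
Il25	IL25
Il27	IL27
Il2ra	IL2RA
Il2rb	IL2RB
Il2rg	IL2RG
Il3	IL3
Il33	IL33
Il34	IL34
Il3ra	IL3RA
Il4	IL4
Il4ra	IL4RA
Il5	IL5
Il5ra	IL5RA
Il6	IL6
Il6ra	IL6RA
Il7	IL7
Il7r	IL7R
Il9	IL9
Irf3	IRF3
Irf4	IRF4
Irf7	IRF7
Irf8	IRF8
Isg15	ISG15
Itga1	ITGA1
Itga2	ITGA2
Itga3	ITGA3
Itga4	ITGA4
Itga5	ITGA5
Itga6	ITGA6
Itgal	ITGAL
Itgam	ITGAM
Itgav	ITGAV
Itgax	ITGAX
Itgb1	ITGB1
Itgb2	ITGB2
Itgb3	ITGB3
Itgb4	ITGB4
Itgb5	ITGB5
Itgb6	ITGB6
Itgb7	ITGB7
Itgb8	ITGB8
Jag1	JAG1
Jag2	JAG2
Jak1	JAK1
Jak2	JAK2
Jak3	JAK3
Jchain	JCHAIN
Jun	JUN
Junb	JUNB
Kdr	KDR
Kit	KIT
Klf1	KLF1
Klf2	KLF2
Klf4	KLF4
Klrb1a	KLRB1A
Klrb1b	KLRB1B
Klrb1c	KLRB1
Klrc1	KLRC1
Klrc2	KLRC2
Klrc3	KLRC3
Klrd1	KLRD1
Klrg1	KLRG1
Klrk1	KLRK1
Lag3	LAG3
Lat	LAT
Lck	LCK
Lcn2	LCN2
Ldha	LDHA
Lef1	LEF1
Lgals3	LGALS3
Lta	LTA
Ltb	LTB
Ltf	LTF
Lum	LUM
Ly6g6c	LY6G6C
Ly75	LY75
Ly86	LY86
Ly9	LY9
Lyz2	LYZ
Madcam1	MADCAM1
Malt1	MALT1
Marco	MARCO
Mavs	MAVS
Mb21d1	CGAS
Mcpt4	MCPT4
Mcpt8	PRSS21
Mertk	MERTK
Mki67	MKI67
Mmp10	MMP10
Mmp11	MMP11
Mmp12	MMP12
Mmp13	MMP13
Mmp14	MMP14
Mmp15	MMP15
Mmp16	MMP16
Mmp17	MMP17
Mmp19	MMP19
Mmp2	MMP2
Mmp3	MMP3
Mmp7	MMP7
Mmp8	MMP8
Mmp9	MMP9
Mpo	MPO
Mrc1	MRC1
Ms4a1	MS4A1
Ms4a2	MS4A2
Msr1	MSR1
Mx1	MX1
Mx2	MX2
Myb	MYB
Myc	MYC
Ncr1	NCR1
Nfkb1	NFKB1
Nfkb2	NFKB2
Nkg7	NKG7
Nlrp3	NLRP3
Nos2	NOS2
Notch1	NOTCH1
Notch2	NOTCH2
Oasl1	OASL1
Olfml3	OLFML3
P2ry12	P2RY12
Pax5	PAX5
Pcna	PCNA
Pdcd1	PDCD1
Pdgfra	PDGFRA
Pdgfrb	PDGFRB
Pecam1	PECAM1
Pkm	PKM
Plcg2	PLCG2
Postn	POSTN
Ppia	PPIA
Prdm1	PRDM1
Prf1	PRF1
Prg2	PRG2
Prkcb	PRKCB
Prtn3	PRTN3
Psmb8	PSMB8
Psmb9	PSMB9
Ptgs1	PTGS1
Ptgs2	PTGS2
Ptprc	PTPRC
Pycard	PYCARD
Rag1	RAG1
Rag2	RAG2
Rel	REL
Rela	RELA
Relb	RELB
Retnlg	RETNLG
Rorc	RORC
Rsad2	RSAD2
Runx1	RUNX1
Runx3	RUNX3
S100a1	S100A1
S100a10	S100A10
S100a11	S100A11
S100a13	S100A13
S100a16	S100A16
S100a4	S100A4
S100a6	S100A6
S100a8	S100A8
S100a9	S100A9
Sall1	SALL1
Sdc1	SDC1
Sdha	SDHA
Sele	SELE
Sell	SELL
Selp	SELP
Siglecf	SIGLEC8
Siglech	SIGLECH
Slamf1	SLAMF1
Slamf2	SLAMF2
Slamf3	SLAMF3
Slamf4	SLAMF4
Slamf5	SLAMF5
Slamf6	SLAMF6
Slamf7	SLAMF7
Slamf8	SLAMF8
Slamf9	SLAMF9
Slc2a1	SLC2A1
Slc4a1	SLC4A1
Slc7a11	SLC7A11
Socs1	SOCS1
Socs3	SOCS3
Sparc	SPARC
Spi1	SPI1
Stat1	STAT1
Stat3	STAT3
Stat4	STAT4
Stat5a	STAT5A
Stat5b	STAT5B
Stat6	STAT6
Syk	SYK
Tagln	TAGLN
Tap1	TAP1
Tap2	TAP2
Tbp	TBP
Tbx21	TBX21
Tcf7	TCF7
Tek	TEK
Tgfb1	TGFB1
Tgfb2	TGFB2
Tgfb3	TGFB3
Thbs1	THBS1
Thbs2	THBS2
Thy1	THY1
Tigit	TIGIT
Timp1	TIMP1
Timp2	TIMP2
Timp3	TIMP3
Timp4	TIMP4
Tlr1	TLR1
Tlr11	TLR11
Tlr12	TLR12
Tlr13	TLR13
Tlr2	TLR2
Tlr3	TLR3
Tlr4	TLR4
Tlr5	TLR5
Tlr6	TLR6
Tlr7	TLR7
Tlr8	TLR8
Tlr9	TLR9
Tmem119	TMEM119
Tmem173	STING1
Tnf	TNF
Tnfaip3	TNFAIP3
Tnfrsf13b	TNFRSF13B
Tnfrsf13c	TNFRSF13C
Tnfrsf14	TNFRSF14
Tnfrsf17	TNFRSF17
Tnfrsf18	TNFRSF18
Tnfrsf1a	TNFRSF1A
Tnfrsf1b	TNFRSF1B
Tnfrsf4	TNFRSF4
Tnfrsf8	TNFRSF8
Tnfrsf9	TNFRSF9
Tnfsf10	TNFSF10
Tnfsf11	TNFSF11
Tnfsf12	TNFSF12
Tnfsf13	TNFSF13
Tnfsf14	TNFSF14
Tnfsf15	TNFSF15
Tnfsf18	TNFSF18
Tnfsf4	TNFSF4
Tnfsf8	TNFSF8
Tnfsf9	TNFSF9
Top2a	TOP2A
Tpsab1	TPSAB1
Traf1	TRAF1
Traf2	TRAF2
Traf3	TRAF3
Traf6	TRAF6
Trem2	TREM2
Tyk2	TYK2
Tyrobp	TYROBP
Usp18	USP18
Vcam1	VCAM1
Vegfa	VEGFA
Vegfb	VEGFB
Vegfc	VEGFC
Vim	VIM
Vpreb1	VPREB1
Vwf	VWF
Wnt5a	WNT5A
Xbp1	XBP1
Xcr1	XCR1
Ywhaz	YWHAZ
Zap70	ZAP70
Zbtb46	ZBTB46
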