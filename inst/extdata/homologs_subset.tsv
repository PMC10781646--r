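mouse	human
Il1a	IL1A
Il1b	IL1B
Il1rn	IL1RN
Il18	IL18
Il33	IL33
Il2	IL2
Il4	IL4
Il4i1	IL4I1
Il13	IL13
Il7	IL7
Il9	IL9
Il15	IL15
Il21	IL21
Il3	IL3
Il5	IL5
Il6	IL6
Il10	IL10
Il12a	IL12A
Il12b	IL12B
Il23a	IL23A
Il27	IL27
Ebi3	EBI3
Il17a	IL17A
Il22	IL22
Ifng	IFNG
Ifnb1	IFNB1
Tnf	TNF
Lta	LTA
Ltb	LTB
Csf1	CSF1
Csf2	CSF2
Csf3	CSF3
Tgfb1	TGFB1
Isg15	ISG15
Ifit1	IFIT1
Ifit3	IFIT3
Irf7	IRF7
Mx1	MX1
Oas1a	OAS1
Rsad2	RSAD2
Stat1	STAT1
Stat2	STAT2
Usp18	USP18
Bst2	BST2
Cxcl9	CXCL9
Cxcl10	CXCL10
Gzmb	GZMB
Prf1	PRF1
Klrg1	KLRG1
Xcl1	XCL1
Myc	MYC
Kit	KIT
Batf	BATF
Ccr7	CCR7
Cd40	CD40
Ccl22	CCL22
Nr4a3	NR4A3
Tnfaip3	TNFAIP3
Ifngr1	IFNGR1
Ifngr2	IFNGR2
Ifnar1	IFNAR1
Ifnar2	IFNAR2
Il1r1	IL1R1
Il1rap	IL1RAP
Il18r1	IL18R1
Il18rap	IL18RAP
Il2rb	IL2RB
Il2rg	IL2RG
Il4ra	IL4R
Tnfrsf1a	TNFRSF1A
Tnfrsf1b	TNFRSF1B
Il12rb1	IL12RB1
Il12rb2	IL12RB2
Retnla	RETNLB
Chchd10	CHCHD10
Glrx	GLRX
Odc1	ODC1
Il1f6	IL36A
Il25	IL25
Hif1a	HIF1A
Ctla4	CTLA4
Cd14	CD14
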