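category	degree	uniprot	gene
direct	75	P03372	ESR1
direct	45	O14757	CHEK1
direct	40	Q16539	MAPK14
direct	28	P07550	ADRB2
direct	16	P29474	NOS3
direct	14	P35968	KDR
direct	11	P35372	OPRM1
direct	6	P10415	BCL2
direct	3	P08588	ADRB1
direct	1	P27169	PON1
direct	1	P14416	DRD2
direct	1	P05164	MPO
direct	1	P03956	MMP1
direct	1	P01130	LDLR
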