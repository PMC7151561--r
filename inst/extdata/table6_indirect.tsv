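category	degree	uniprot	gene
indirect	5	P60568	IL2
indirect	5	O14746	TERT
indirect	4	Q9UJU2	LEF1
indirect	3	Q03468	ERCC6
indirect	3	P69905	HBA2
indirect	2	P62736	ACTA2
indirect	2	P16473	TSHR
indirect	2	P04035	HMGCR
indirect	2	P02741	CRP
indirect	1	Q9UBP4	DKK3
indirect	1	Q9H3N8	HRH4
indirect	1	Q9H3D4	TP63
indirect	1	Q14790	CASP8
indirect	1	Q12988	HSPB3
indirect	1	P84022	SMAD3
indirect	1	P57071	PRDM15
indirect	1	P42345	MTOR
indirect	1	P35568	IRS1
indirect	1	P30874	SSTR2
indirect	1	P25391	LAMA1
indirect	1	P18074	ERCC2
indirect	1	P08183	ABCB1
indirect	1	P05556	ITGB1
indirect	1	P04626	ERBB2
indirect	1	P01889	HLA-B
indirect	1	P00519	ABL1
indirect	1	O60469	DSCAM
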