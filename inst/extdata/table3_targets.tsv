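target_id	gene	protein	degree
P10275	AR	Androgen receptor	83
P03372	ESR1	Estrogen receptor	74
P00918	CA2	Carbonic anhydrase 2	60
P37231	PPARG	Peroxisome proliferator-activated receptor gamma	56
P35354	PTGS2	Prostaglandin G/H synthase 2	56
P35228	NOS2	Nitric oxide synthase, inducible	53
P00734	F2	Prothrombin	49
P27487	DPP4	Dipeptidyl peptidase 4	49
Q92731	ESR2	Estrogen receptor beta	47
Q07785	CRK2	Cell division control protein 2 homolog	45
P49841	GSK3B	Glycogen synthase kinase-3 beta	46
O14757	CHEK1	Serine/threonine-protein kinase Chk1	45
P18031	PTPN1	Tyrosine-protein phosphatase non-receptor type 1	43
Q16539	MAPK14	Mitogen-activated protein kinase 14	39
P07900	HSP90AA1	Heat shock protein HSP 90-alpha	38
P08238	HSP90AB1	Heat shock protein HSP 90-beta	37
P23219	PTGS1	Prostaglandin G/H synthase 1	32
P00742	F10	Coagulation factor X	31
Q14524	SCN5A	Sodium channel protein type 5 subunit alpha	30
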