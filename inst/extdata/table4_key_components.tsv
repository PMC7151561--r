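herbs	mol_id	name	degree
FR,PR,AT	MOL000358	Beta-sitosterol	17
PR	MOL000422	Kaempferol	14
AT	MOL002670	Cavidine	13
CR,LO	MOL004328	Naringenin	12
LO	MOL000392	Formononetin	11
AC	MOL012922	l-SPD	11
AT	MOL002714	Baicalein	10
AT,AC	MOL000449	Stigmasterol	10
LO	MOL005003	Licoagrocarpin	10
LO	MOL004959	1-Methoxyphaseollidin	10
LO,AC	MOL004908	Glabridin	10
LO	MOL004891	Shinpterocarpin	10
AC	MOL004841	Licochalcone B	10
LO	MOL001484	Inermine	10
AC	MOL010921	Estrone	10
AC,PR	MOL000492	(+)-catechin	9
CR	MOL005828	Nobiletin	9
LO,AC	MOL005017	Phaseol	9
LO	MOL005000	Gancaonin G	9
LO	MOL004941	(2R)-7-hydroxy-2-(4-Hydroxyphenyl)chroman-4-one	9
LO	MOL004849	3-(2,4-dihydroxyphenyl)-8-(1,1-Dimethylprop-2-enyl)-7-hydroxy-5-methoxy-coumarin	9
LO	MOL004835	Glypallichalcone	9
LO	MOL004829	Glepidotin B	9
LO	MOL004824	(2S)-6-(2,4-dihydroxyphenyl)-2-(2-hydroxypropan-2-yl)-4-methoxy-2,3-dihydrofuro[3,2-g]chromen-7-one	9
AC	MOL007207	Machiline	9
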