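herbs	name	mol_id	degree
FR,PR,AT	Beta-sitosterol	MOL000358	49
PR	Kaempferol	MOL000422	44
AC	L-SPD	MOL012922	44
AT	Cavidine	MOL002670	43
AC,AT	Stigmasterol	MOL000449	39
AC	Estrone	MOL010921	34
AC	Machiline	MOL007207	32
LO	Shinpterocarpin	MOL004891	30
LO	Formononetin	MOL000392	30
LO	Naringenin	MOL004328	29
LO,CR	1-Methoxyphaseollidin	MOL004959	28
LO	Licoagrocarpin	MOL005003	28
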