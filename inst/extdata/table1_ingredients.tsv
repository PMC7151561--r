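id	mol_id	name	ob	dl	herbs
ID001	MOL000359	sitosterol	36.91	0.75	CR,PR,FR,AC
ID002	MOL004328	naringenin	59.29	0.21	CR,LO
ID003	MOL005100	5,7-dihydroxy-2-(3-hydroxy-4-methoxyphenyl)chroman-4-one	47.74	0.27	CR
ID004	MOL005815	Citromitin	86.9	0.51	CR
ID005	MOL005828	nobiletin	61.67	0.52	CR
ID006	MOL001755	24-Ethylcholest-4-en-3-one	36.08	0.76	AT
ID007	MOL002670	Cavidine	35.64	0.81	AT
ID008	MOL002714	baicalein	33.52	0.21	AT
ID009	MOL002776	Baicalin	40.12	0.75	AT
ID010	MOL000358	beta-sitosterol	36.91	0.75	AT,FR,PR
ID011	MOL000449	Stigmasterol	43.83	0.76	AT,AC
ID012	MOL005030	gondoic acid	30.7	0.2	AT,AC
ID013	MOL000519	coniferin	31.11	0.32	AT
ID014	MOL006936	10,13-eicosadienoic	39.99	0.2	AT
ID015	MOL006937	12,13-epoxy-9-hydroxynonadeca-7,10-dienoic acid	42.15	0.24	AT
ID016	MOL006957	(3S,6S)-3-(benzyl)-6-(4-hydroxybenzyl)piperazine-2,5-quinone	46.89	0.27	AT
ID017	MOL003578	Cycloartenol	38.69	0.78	AT
ID018	MOL006967	beta-D-Ribofuranoside, xanthine-9	44.72	0.21	AT
ID019	MOL001910	11alpha,12alpha-epoxy-3beta-23-dihydroxy-30-norolean-20-en-28,12beta-olide	64.77	0.38	PR
ID020	MOL001918	paeoniflorgenone	87.59	0.37	PR
ID021	MOL001919	(3S,5R,8R,9R,10S,14S)-3,17-dihydroxy-4,4,8,10,14-pentamethyl-2,3,5,6,7,9-hexahydro-1H-cyclopenta[a]phenanthrene-15,16-dione	43.56	0.53	PR
ID022	MOL001921	Lactiflorin	49.12	0.8	PR
ID023	MOL001924	paeoniflorin	53.87	0.79	PR
ID024	MOL001925	paeoniflorin_qt	68.18	0.4	PR
ID025	MOL001928	albiflorin_qt	66.64	0.33	PR
ID026	MOL001930	benzoyl paeoniflorin	31.27	0.75	PR
ID027	MOL000211	Mairin	55.38	0.78	PR,LO,AC
ID028	MOL000422	kaempferol	41.88	0.24	PR
ID029	MOL000492	(+)-catechin	54.83	0.24	PR,AC
ID030	MOL004624	Longikaurin A	47.72	0.53	SC
ID031	MOL005317	Deoxyharringtonine	39.27	0.81	SC
ID032	MOL008956	Angeloylgomisin O	31.97	0.85	SC
ID033	MOL008957	Schizandrer B	30.71	0.83	SC
ID034	MOL008968	Gomisin-A	30.69	0.78	SC
ID035	MOL008974	Gomisin G	32.68	0.83	SC
ID036	MOL008978	Gomisin R	34.84	0.86	SC
ID037	MOL008992	Wuweizisu C	46.27	0.84	SC
ID038	MOL001749	ZINC03860434	43.59	0.35	FR
ID039	MOL004440	Peimisine	57.4	0.81	FR
ID040	MOL009027	Cyclopamine	55.42	0.82	FR
ID041	MOL009572	Chuanbeinone	41.07	0.71	FR
ID042	MOL009579	ent-(16S)-atisan-13,17-oxide	47.74	0.43	FR
ID043	MOL009586	isoverticine	48.23	0.67	FR
ID044	MOL009588	Korseveriline	35.16	0.68	FR
ID045	MOL009589	Korseverinine	53.51	0.71	FR
ID046	MOL009593	verticinone	60.07	0.67	FR
ID047	MOL009596	sinpemine A	46.96	0.71	FR
ID048	MOL009599	songbeinone	45.35	0.71	FR
ID049	MOL010921	estrone	53.56	0.32	AC
ID050	MOL010922	Diisooctyl succinate	31.62	0.23	AC
ID051	MOL002211	11,14-eicosadienoic acid	39.99	0.2	AC
ID052	MOL002372	(6Z,10E,14E,18E)-2,6,10,15,19,23-hexamethyltetracosa-2,6,10,14,18,22-hexaene	33.55	0.42	AC
ID053	MOL000953	CLR	37.87	0.68	AC
ID054	MOL002311	Glycyrol	90.78	0.67	AC,LO
ID055	MOL003410	Ziziphin_qt	66.95	0.62	AC
ID056	MOL004355	Spinasterol	42.98	0.76	AC
ID057	MOL004841	Licochalcone B	76.76	0.19	AC,LO
ID058	MOL004903	liquiritin	65.69	0.74	AC,LO
ID059	MOL004908	Glabridin	53.25	0.47	AC,LO
ID060	MOL005017	Phaseol	78.77	0.58	AC,LO
ID061	MOL007207	Machiline	79.64	0.24	AC
ID062	MOL012922	l-SPD	87.35	0.54	AC
ID063	MOL000273	(2R)-2-[(3S,5R,10S,13R,14R,16R,17R)-3,16-dihydroxy-4,4,10,13,14-pentamethyl-2,3,5,6,12,15,16,17-octahydro-1H-cyclopenta[a]phenanthren-17-yl]-6-methylhept-5-enoic acid	30.93	0.81	PC
ID064	MOL000275	trametenolic acid	38.71	0.8	PC
ID065	MOL000276	7,9(11)-dehydropachymic acid	35.11	0.81	PC
ID066	MOL000279	Cerevisterol	37.96	0.77	PC
ID067	MOL000280	(2R)-2-[(3S,5R,10S,13R,14R,16R,17R)-3,16-dihydroxy-4,4,10,13,14-pentamethyl-2,3,5,6,12,15,16,17-octahydro-1H-cyclopenta[a]phenanthren-17-yl]-5-isopropyl-hex-5-enoic acid	31.07	0.82	PC
ID068	MOL000282	ergosta-7,22E-dien-3beta-ol	43.51	0.72	PC
ID069	MOL000283	Ergosterol peroxide	40.36	0.81	PC
ID070	MOL000285	(2R)-2-[(5R,10S,13R,14R,16R,17R)-16-hydroxy-3-keto-4,4,10,13,14-pentamethyl-1,2,5,6,12,15,16,17-octahydrocyclopenta[a]phenanthren-17-yl]-5-isopropyl-hex-5-enoic acid	38.26	0.82	PC
ID071	MOL000287	3beta-Hydroxy-24-methylene-8-lanostene-21-oic acid	38.7	0.81	PC
ID072	MOL000289	pachymic acid	33.63	0.81	PC
ID073	MOL000290	Poricoic acid A	30.61	0.76	PC
ID074	MOL000291	Poricoic acid B	30.52	0.75	PC
ID075	MOL000292	poricoic acid C	38.15	0.75	PC
ID076	MOL000296	hederagenin	36.91	0.75	PC
ID077	MOL000300	dehydroeburicoic acid	44.17	0.83	PC
ID078	MOL005020	dehydroglyasperins C	53.82	0.37	LO
ID079	MOL005018	Xambioona	54.85	0.87	LO
ID080	MOL005012	Licoagroisoflavone	57.28	0.49	LO
ID081	MOL005007	Glyasperins M	72.67	0.59	LO
ID082	MOL005003	Licoagrocarpin	58.81	0.58	LO
ID083	MOL005001	Gancaonin H	50.1	0.78	LO
ID084	MOL005000	Gancaonin G	60.44	0.39	LO
ID085	MOL004993	8-prenylated eriodictyol	53.79	0.4	LO
ID086	MOL004990	7,2′,4′-trihydroxy-5-methoxy-3-arylcoumarin	83.71	0.27	LO
ID087	MOL004959	1-Methoxyphaseollidin	69.98	0.64	LO
ID088	MOL004941	(2R)-7-hydroxy-2-(4-hydroxyphenyl)chroman-4-one	71.12	0.18	LO
ID089	MOL004914	1,3-dihydroxy-8,9-dimethoxy-6-benzofurano[3,2-c]chromenone	62.9	0.53	LO
ID090	MOL004912	Glabrone	52.51	0.5	LO
ID091	MOL004910	Glabranin	52.9	0.31	LO
ID092	MOL004907	Glyzaglabrin	61.07	0.35	LO
ID093	MOL004904	licopyranocoumarin	80.36	0.65	LO
ID094	MOL004891	shinpterocarpin	80.3	0.73	LO
ID095	MOL004885	licoisoflavanone	52.47	0.54	LO
ID096	MOL004879	Glycyrin	52.61	0.47	LO
ID097	MOL004863	3-(3,4-dihydroxyphenyl)-5,7-dihydroxy-8-(3-methylbut-2-enyl)chromone	66.37	0.41	LO
ID098	MOL004856	Gancaonin A	51.08	0.4	LO
ID099	MOL004855	Licoricone	63.58	0.47	LO
ID100	MOL004849	3-(2,4-dihydroxyphenyl)-8-(1,1-dimethylprop-2-enyl)-7-hydroxy-5-methoxy-coumarin	59.62	0.43	LO
ID101	MOL004838	8-(6-hydroxy-2-benzofuranyl)-2,2-dimethyl-5-chromenol	58.44	0.38	LO
ID102	MOL004835	Glypallichalcone	61.6	0.19	LO
ID103	MOL004829	Glepidotin B	64.46	0.34	LO
ID104	MOL004824	(2S)-6-(2,4-dihydroxyphenyl)-2-(2-hydroxypropan-2-yl)-4-methoxy-2,3-dihydrofuro[3,2-g]chromen-7-one	60.25	0.63	LO
ID105	MOL004820	kanzonols W	50.48	0.52	LO
ID106	MOL004810	glyasperin F	75.84	0.54	LO
ID107	MOL004808	glyasperin B	65.22	0.44	LO
ID108	MOL003656	Lupiwighteone	51.64	0.37	LO
ID109	MOL001484	Inermine	75.18	0.54	LO
ID110	MOL000500	Vestitol	74.66	0.21	LO
ID111	MOL000392	formononetin	69.67	0.21	LO
ID112	MOL000239	Jaranol	50.83	0.29	LO
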