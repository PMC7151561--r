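gene	Bone Marrow	Whole Blood	Lymph Node	Thymus	Tonsil	Myeloid	Monocytes	Dentritic Cells	NK cells	T Cells(CD+4)	T Cells(CD+8)	B-Lymphoblasts	B Cells	Endothelial
HLA-B	268	689	316	229	302	630	577	558	716	514	512	410	411	154
CASP8	6	12	8	6	6	11	9	8	13	16	15	7	8	6
MAPK14	5	13	3	3	3	21	13	10	10	7	7	8	5	5
SMAD3	4	4	4	4	4	5	5	6	5	7	5	5	8	4
ACTA2	8	9	23	17	11	9	8	6	8	6	7	12	7	5
ADRB2	10	25	3	2	3	22	9	6	41	5	14	3	3	3
BCL2	5	6	6	4	5	6	5	5	7	11	8	9	11	6
LEF1	4	9	8	35	6	4	4	4	5	30	27	4	4	4
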