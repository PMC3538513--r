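name	smiles	nC	nN	nO	nS	nAtoms	nRings	MW	nHBDon	Wiener	Harary
methane	C	1	0	0	0	1	0	16.043	0	0.0	0.0
ethane	CC	2	0	0	0	2	0	30.07	0	1.0	1.0
propane	CCC	3	0	0	0	3	0	44.097	0	4.0	2.5
n-butane	CCCC	4	0	0	0	4	0	58.124	0	10.0	4.333333
isobutane	CC(C)C	4	0	0	0	4	0	58.124	0	9.0	4.5
n-hexane	CCCCCC	6	0	0	0	6	0	86.178	0	35.0	8.7
cyclopropane	C1CC1	3	0	0	0	3	1	42.081	0	3.0	3.0
cyclohexane	C1CCCCC1	6	0	0	0	6	1	84.162	0	27.0	10.0
ethene	C=C	2	0	0	0	2	0	28.054	0	1.0	1.0
acetonitrile	CC#N	2	1	0	0	3	0	41.053	0	4.0	2.5
benzene	c1ccccc1	6	0	0	0	6	1	78.114	0	27.0	10.0
toluene	Cc1ccccc1	7	0	0	0	7	1	92.141	0	42.0	12.916667
phenol	Oc1ccccc1	6	0	1	0	7	1	94.113	1	42.0	12.916667
aniline	Nc1ccccc1	6	1	0	0	7	1	93.129	1	42.0	12.916667
pyridine	c1ccncc1	5	1	0	0	6	1	79.102	0	27.0	10.0
pyrrole	c1cc[nH]c1	4	1	0	0	5	1	67.091	1	15.0	7.5
furan	c1ccoc1	4	0	1	0	5	1	68.075	0	15.0	7.5
thiophene	c1ccsc1	4	0	0	1	5	1	84.143	0	15.0	7.5
imidazole	c1c[nH]cn1	3	2	0	0	5	1	68.079	1	15.0	7.5
naphthalene	c1ccc2ccccc2c1	10	0	0	0	10	2	128.174	0	109.0	23.9
ethanol	CCO	2	0	1	0	3	0	46.069	1	4.0	2.5
acetic-acid	CC(=O)O	2	0	2	0	4	0	60.052	1	9.0	4.5
acetamide	CC(=O)N	2	1	1	0	4	0	59.068	1	9.0	4.5
ethanethiol	CCS	2	0	0	1	3	0	62.137	0	4.0	2.5
aspirin	CC(=O)Oc1ccccc1C(=O)O	9	0	4	0	13	1	180.159	1	246.0	33.783333
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	8	4	2	0	14	2	194.194	0	258.0	41.35
ibuprofen	CC(C)Cc1ccc(C(C)C(=O)O)cc1	13	0	2	0	15	1	206.285	1	404.0	40.951587
anilinoquinazoline	c1ccc(Nc2ncnc3ccccc23)cc1	14	3	0	0	17	3	221.263	1	518.0	52.45754
tetramethylammonium	C[N+](C)(C)C	4	1	0	0	5	0	74.147	0	16.0	7.0
acetate	CC(=O)[O-]	2	0	2	0	4	0	59.044	0	9.0	4.5
dimethylselenide	C[Se]C	2	0	0	0	3	0	109.03	0	4.0	2.5
ethanolamine	NCCO	2	1	1	0	4	0	61.084	2	10.0	4.333333
benzenesulfonamide	NS(=O)(=O)c1ccccc1	6	1	2	1	10	1	157.194	1	114.0	23.016667
benzotrifluoride	FC(F)(F)c1ccccc1	7	0	0	0	10	1	146.111	0	114.0	23.016667
chlorobenzene	Clc1ccccc1	6	0	0	0	7	1	112.559	0	42.0	12.916667
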