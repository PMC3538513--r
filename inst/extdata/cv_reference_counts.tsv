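engine	fold	train_pos	test_pos	TP	FN	SE	train_neg	test_neg	TN	FP	SP	Q	C
svm	1	1362	341	320	21	93.84	50654	12664	12651	13	99.90	99.74	0.948
svm	2	1362	341	324	17	95.01	50654	12664	12650	14	99.89	99.76	0.953
svm	3	1362	341	324	17	95.01	50654	12664	12640	24	99.81	99.68	0.939
svm	4	1363	340	318	22	93.53	50655	12663	12642	21	99.83	99.67	0.935
svm	5	1363	340	322	18	94.71	50655	12663	12643	20	99.84	99.71	0.943
knn	1	1362	341	302	39	88.56	50654	12664	12635	29	99.77	99.48	0.896
knn	2	1362	341	313	28	91.79	50654	12664	12620	44	99.65	99.45	0.894
knn	3	1362	341	311	30	91.20	50654	12664	12610	54	99.57	99.35	0.878
knn	4	1363	340	316	24	92.94	50655	12663	12619	44	99.65	99.48	0.901
knn	5	1363	340	302	38	88.82	50655	12663	12632	31	99.76	99.47	0.895
pnn	1	1362	341	319	22	93.55	50654	12664	12413	251	98.02	97.90	0.715
pnn	2	1362	341	324	17	95.01	50654	12664	12380	284	97.76	97.69	0.702
pnn	3	1362	341	330	11	96.77	50654	12664	12395	269	97.88	97.85	0.722
pnn	4	1363	340	330	10	97.06	50655	12663	12389	274	97.84	97.82	0.720
pnn	5	1363	340	318	22	93.53	50655	12663	12413	250	98.03	97.91	0.715
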