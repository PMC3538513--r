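engine	stat	SE	SP	Q	C
svm	mean	94.42	99.85	99.71	0.944
svm	sd	0.0069	0.0004	0.0004	0.0072
svm	se	0.0031	0.0002	0.0002	0.0032
knn	mean	90.66	99.68	99.44	0.893
knn	sd	0.0191	0.0008	0.0005	0.0085
knn	se	0.0085	0.0004	0.0002	0.0038
pnn	mean	95.19	97.90	97.83	0.715
pnn	sd	0.0169	0.0012	0.0009	0.0075
pnn	se	0.0076	0.0005	0.0004	0.0034
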