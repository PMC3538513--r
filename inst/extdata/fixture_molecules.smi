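C methane
CC ethane
CCC propane
CCCC n-butane
CC(C)C isobutane
CCCCCC n-hexane
C1CC1 cyclopropane
C1CCCCC1 cyclohexane
C=C ethene
CC#N acetonitrile
c1ccccc1 benzene
Cc1ccccc1 toluene
Oc1ccccc1 phenol
Nc1ccccc1 aniline
c1ccncc1 pyridine
c1cc[nH]c1 pyrrole
c1ccoc1 furan
c1ccsc1 thiophene
c1c[nH]cn1 imidazole
c1ccc2ccccc2c1 naphthalene
CCO ethanol
CC(=O)O acetic-acid
CC(=O)N acetamide
CCS ethanethiol
CC(=O)Oc1ccccc1C(=O)O aspirin
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
CC(C)Cc1ccc(C(C)C(=O)O)cc1 ibuprofen
c1ccc(Nc2ncnc3ccccc23)cc1 anilinoquinazoline
C[N+](C)(C)C tetramethylammonium
CC(=O)[O-] acetate
C[Se]C dimethylselenide
NCCO ethanolamine
NS(=O)(=O)c1ccccc1 benzenesulfonamide
FC(F)(F)c1ccccc1 benzotrifluoride
Clc1ccccc1 chlorobenzene
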