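CCO ethanol
OCCN ethanolamine
c1ccccc1 benzene
Cc1ccccc1 toluene
c1ccc(Cl)cc1 chlorobenzene
c1ccncc1 pyridine
c1cc[nH]c1 pyrrole
c1ccsc1 thiophene
c1ccoc1 furan
CC(=O)Nc1ccccc1 acetanilide
NC(=O)c1ccccc1 benzamide
OC(=O)c1ccc(O)cc1 hydroxybenzoic
CN1CCN(c2ccccc2)CC1 phenylpiperazine
C1CCNCC1 piperidine
FC(F)(F)c1ccccc1 trifluorotoluene
N#Cc1ccccc1 benzonitrile
CS(=O)(=O)N methanesulfonamide
CCSC thioether
C=CC=O acrolein
CN=Cc1ccccc1 imine
C[N+](C)(C)C tetramethylammonium
[NH3+]CCO protonated_ethanolamine
c1ccc2ccccc2c1 naphthalene
c1ccc2[nH]ccc2c1 indole
Clc1ccc(CN2CCN(CC2)c2ncccc2)cc1 arylpiperazine_big
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
CN1CCC(CC1)c1c[nH]c2ccccc12 tryptamine_like
O=C(O)CCc1c[nH]cn1 histidine_like
COc1ccc(CCN)cc1 methoxyphenethylamine
OCC1OC(O)C(O)C(O)C1O sugar_like
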