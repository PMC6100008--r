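# Demo substructure key set (Klekota-Roth-flavoured SMARTS, supported subset)
KR001	[OX2H]
KR002	[OX2H0]
KR003	[NX3;H2]
KR004	[NX3;H1]
KR005	[NX3;H0]
KR006	[N+]
KR007	c1ccccc1
KR008	c1ccncc1
KR009	[nH]
KR010	[nX2]
KR011	c1ccsc1
KR012	c1ccoc1
KR013	[CX3]=[OX1]
KR014	[CX3](=[OX1])[NX3]
KR015	[CX3](=[OX1])[OX2H]
KR016	[CX3](=[OX1])[OX2H0]
KR017	[CX4H3]
KR018	[CX4H2]
KR019	[CX4H1]
KR020	[CX4H0]
KR021	[F,Cl,Br,I]
KR022	Clc1ccccc1
KR023	Fc1ccccc1
KR024	[CX4]F
KR025	C(F)(F)F
KR026	[SX2]
KR027	[#16X4](=[OX1])(=[OX1])
KR028	[CX2]#[NX1]
KR029	[CX3]=[CX3]
KR030	[NX2]=[CX3]
KR031	c[NX3]
KR032	c[OX2H]
KR033	[cH0]
KR034	[C;R]
KR035	[N;R]
KR036	[O;R]
KR037	C1CCNCC1
KR038	N1CCNCC1
KR039	[CX4][NX3]
KR040	[OX2][CX4]
KR041	[cX3][CX4]
KR042	[NX3][CX3]=[OX1]
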