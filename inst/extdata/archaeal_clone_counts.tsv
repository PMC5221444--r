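cluster	metabolism	consortium	timepoint	count
Methanosarcina mazei	acetoclastic+hydrogenotrophic	N12	t2	10
Methanosarcina thermophila	acetoclastic+hydrogenotrophic	Wp2a	t2	1
Methanosarcina vacuolata	acetoclastic+hydrogenotrophic	Wp2a	t2	9
Methanosarcina sp.	acetoclastic+hydrogenotrophic	Wp2a	t2	1
Methanosaeta concilii	acetoclastic	Ap1a	t2	1
Methanosaeta harundinacea	acetoclastic	Ap1a	t2	1
Methanobacterium petrolearium	hydrogenotrophic	N12	t2	1
Methanoculleus marisnigri	hydrogenotrophic	G12	t2	2
Methanoculleus receptaculi	hydrogenotrophic	Ap1a	t2	4
Methanoculleus receptaculi	hydrogenotrophic	G12	t2	5
Methanoculleus sp.	hydrogenotrophic	Ap1a	t2	1
Methanomethylovorans hollandica	neither	Ap1a	t2	1
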