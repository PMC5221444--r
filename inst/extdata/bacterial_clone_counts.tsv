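cluster	consortium	timepoint	count
Syntrophobacter sulfatireducens	Ap1a	t2	15
Syntrophobacter sulfatireducens	Ap1a	t3	16
Cryptanaerobacter sp./Pelotomaculum sp.	N12	t2	14
Cryptanaerobacter sp./Pelotomaculum sp.	N12	t3	26
Cryptanaerobacter sp./Pelotomaculum sp.	Wp2a	t1	16
Cryptanaerobacter sp./Pelotomaculum sp.	Wp2a	t2	33
Cryptanaerobacter sp./Pelotomaculum sp.	Wp2a	t3	27
Candidatus Cloacamonas sp.	Ap1a	t1	2
Candidatus Cloacamonas sp.	Ap1a	t2	3
Candidatus Cloacamonas sp.	Ap1a	t3	2
Candidatus Cloacamonas sp.	Wp2a	t2	1
Candidatus Cloacamonas sp.	Wp2a	t3	9
Tepidanaerobacter acetatoxydans	Ap1a	t1	15
Tepidanaerobacter acetatoxydans	Ap1a	t2	7
Tepidanaerobacter acetatoxydans	Ap1a	t3	2
Tepidanaerobacter acetatoxydans	G12	t1	32
Tepidanaerobacter acetatoxydans	G12	t2	19
Tepidanaerobacter acetatoxydans	G12	t3	5
Tepidanaerobacter acetatoxydans	N12	t1	12
Tepidanaerobacter acetatoxydans	N12	t2	4
Tepidanaerobacter acetatoxydans	N12	t3	2
Tepidanaerobacter acetatoxydans	Wp2a	t1	18
Tepidanaerobacter acetatoxydans	Wp2a	t2	4
Tepidanaerobacter acetatoxydans	Wp2a	t3	3
Desulfovibrio aminophilus	G12	t1	4
Desulfovibrio aminophilus	G12	t2	8
Desulfovibrio aminophilus	G12	t3	24
Desulfovibrio aminophilus	N12	t1	7
Desulfovibrio aminophilus	N12	t2	3
Desulfovibrio aminophilus	N12	t3	1
Caloramator sp./Moorella sp.	N12	t1	1
Caloramator sp./Moorella sp.	N12	t2	1
Caloramator sp./Moorella sp.	N12	t3	2
Syntrophaceticus sp./Thermacetogenium sp.	N12	t2	13
Syntrophaceticus sp./Thermacetogenium sp.	N12	t3	2
Aminobacterium colombiense	Ap1a	t1	24
Aminobacterium colombiense	Ap1a	t2	6
Aminobacterium colombiense	Ap1a	t3	20
Aminobacterium colombiense	N12	t1	1
Aminobacterium colombiense	N12	t2	2
Aminobacterium colombiense	N12	t3	1
Aminobacterium colombiense	Wp2a	t1	4
Aminobacterium colombiense	Wp2a	t2	7
Aminobacterium colombiense	Wp2a	t3	2
Sedimentibacter sp.	N12	t1	6
Sedimentibacter sp.	N12	t3	1
Defluviitoga tunisiensis	N12	t1	2
Defluviitoga tunisiensis	N12	t2	1
Defluviitoga tunisiensis	N12	t3	1
Defluviitoga tunisiensis	Wp2a	t1	2
Defluviitoga tunisiensis	Wp2a	t2	2
Defluviitoga tunisiensis	Wp2a	t3	1
Mesotoga infera	Ap1a	t1	1
Mesotoga infera	Ap1a	t2	1
Mesotoga infera	Ap1a	t3	3
Mesotoga infera	G12	t1	1
Mesotoga infera	G12	t2	2
Mesotoga infera	G12	t3	2
Mesotoga infera	Wp2a	t1	1
Mesotoga infera	Wp2a	t2	2
Mesotoga infera	Wp2a	t3	1
Ornatilinea sp.	Wp2a	t1	1
Ornatilinea sp.	Wp2a	t2	1
Ornatilinea sp.	Wp2a	t3	1
Treponema sp.	Ap1a	t1	11
Treponema sp.	Ap1a	t2	14
Treponema sp.	Ap1a	t3	2
Treponema sp.	G12	t1	14
Treponema sp.	G12	t2	15
Treponema sp.	G12	t3	6
Treponema sp.	N12	t1	13
Treponema sp.	N12	t2	6
Treponema sp.	N12	t3	3
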