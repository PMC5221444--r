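cluster	guild
Syntrophobacter sulfatireducens	propionate-oxidizing
Cryptanaerobacter sp./Pelotomaculum sp.	propionate-oxidizing
Candidatus Cloacamonas sp.	propionate-oxidizing
Tepidanaerobacter acetatoxydans	acetate-oxidizing
Desulfovibrio aminophilus	H2-oxidizing
Caloramator sp./Moorella sp.	H2-oxidizing
Syntrophaceticus sp./Thermacetogenium sp.	H2-oxidizing
Aminobacterium colombiense	propionate-forming
Sedimentibacter sp.	propionate-forming
Defluviitoga tunisiensis	sugar-metabolizing
Mesotoga infera	sugar-metabolizing
Ornatilinea sp.	sugar-metabolizing
Treponema sp.	sugar-metabolizing
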