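synonym	code	source
Globigerina digitata	Beella_digitata	table
Globigerinella digitata	Beella_digitata	table
Globigerinita pumilio	Berggrenia_pumilio	table
Dentagloborotalia anfracta	Dentigloborotalia_anfracta	table
Globorotalia anfracta	Dentigloborotalia_anfracta	table
Globigerina calida	Globigerinella_calida	table
Globigerinella aequilateralis	Globigerinella_siphonifera	table
Globigerinita bradyi	Globigerinita_uvula	table
Globoturborotalita tenella	Globigerinoides_tenellus	table
Globorotalia inflata	Globoconella_inflata	table
Globorotalia menardii flexuosa	Globorotalia_menardii	table
Globorotalia tumida flexuosa	Globorotalia_tumida	table
Globoquadrina hexagona	Globorotaloides_hexagonus	table
Globigerina rubescens	Globoturborotalita_rubescens	table
Hastigerina digitata	Hastigerinella_digitata	table
Globigerina pachyderma	Neogloboquadrina_pachyderma	table
Neogloboquadrina pachyderma sinistral	Neogloboquadrina_pachyderma	table
Globoquadrina dutertrei	Neogloboquadrina_dutertrei	table
Neogloboquadrina pachyderma dextral	Neogloboquadrina_incompta	table
Globigerinita iota	Tenuitella_iota	table
Globigerinoides sacculifer	Trilobatus_sacculifer	table
Globigerinoides trilobus	Trilobatus_sacculifer	table
Globigerina humilis	Turborotalita_humilis	table
Turborotalia cristata	Turborotalita_humilis	table
Turborotalia humilis	Turborotalita_humilis	table
Globigerina quinqueloba	Turborotalita_quinqueloba	table
Turborotalia quinqueloba	Turborotalita_quinqueloba	table
Globigerinoides ruber	Globigerinoides_ruber_pw	alias
Globigerinoides ruber pink and white	Globigerinoides_ruber_pw	alias
Globorotalia menardii and Globorotalia tumida	Globorotalia_menardii_tumida	alias
Turborotalita humilis and Berggrenia pumilio	Turborotalita_humilis_Berggrenia_pumilio	alias
Globorotalia truncatulinoides dextral coiling	Globorotalia_truncatulinoides_dex	alias
Globorotalia truncatulinoides sinistral coiling	Globorotalia_truncatulinoides_sin	alias
Turborotalita quinqueloba dextral coiling	Turborotalita_quinqueloba_dex	alias
Turborotalita quinqueloba sinistral coiling	Turborotalita_quinqueloba_sin	alias
Neogloboquadrina pachyderma s	Neogloboquadrina_pachyderma	alias
Neogloboquadrina pachyderma d	Neogloboquadrina_incompta	alias
unidentified	unidentified	alias
Unidentified	unidentified	alias
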