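code	genus	species	kind	parent	recorded	display
Dentigloborotalia_anfracta	Dentigloborotalia	anfracta	species		TRUE	Dentigloborotalia anfracta
Globorotalia_cavernula	Globorotalia	cavernula	species		TRUE	Globorotalia cavernula
Globorotalia_crassaformis	Globorotalia	crassaformis	species		TRUE	Globorotalia crassaformis
Globorotalia_hirsuta	Globorotalia	hirsuta	species		TRUE	Globorotalia hirsuta
Globorotalia_menardii	Globorotalia	menardii	species		TRUE	Globorotalia menardii
Globorotalia_scitula	Globorotalia	scitula	species		TRUE	Globorotalia scitula
Globorotalia_truncatulinoides	Globorotalia	truncatulinoides	species		TRUE	Globorotalia truncatulinoides
Globorotalia_tumida	Globorotalia	tumida	species		TRUE	Globorotalia tumida
Globorotalia_ungulata	Globorotalia	ungulata	species		TRUE	Globorotalia ungulata
Globorotalia_theyeri	Globorotalia	theyeri	species		TRUE	Globorotalia theyeri
Globoconella_inflata	Globoconella	inflata	species		TRUE	Globoconella inflata
Neogloboquadrina_dutertrei	Neogloboquadrina	dutertrei	species		TRUE	Neogloboquadrina dutertrei
Neogloboquadrina_incompta	Neogloboquadrina	incompta	species		TRUE	Neogloboquadrina incompta
Neogloboquadrina_pachyderma	Neogloboquadrina	pachyderma	species		TRUE	Neogloboquadrina pachyderma
Pulleniatina_obliquiloculata	Pulleniatina	obliquiloculata	species		TRUE	Pulleniatina obliquiloculata
Globoquadrina_conglomerata	Globoquadrina	conglomerata	species		TRUE	Globoquadrina conglomerata
Globorotaloides_hexagonus	Globorotaloides	hexagonus	species		TRUE	Globorotaloides hexagonus
Berggrenia_pumilio	Berggrenia	pumilio	species		TRUE	Berggrenia pumilio
Globigerina_bulloides	Globigerina	bulloides	species		TRUE	Globigerina bulloides
Globigerina_falconensis	Globigerina	falconensis	species		TRUE	Globigerina falconensis
Globigerinoides_conglobatus	Globigerinoides	conglobatus	species		TRUE	Globigerinoides conglobatus
Globigerinoides_ruber_pink	Globigerinoides	ruber (pink)	species		TRUE	Globigerinoides ruber (pink)
Globigerinoides_ruber_white	Globigerinoides	ruber (white)	species		TRUE	Globigerinoides ruber (white)
Trilobatus_sacculifer	Trilobatus	sacculifer	species		TRUE	Trilobatus sacculifer
Globigerinoides_tenellus	Globigerinoides	tenellus	species		TRUE	Globigerinoides tenellus
Orbulina_universa	Orbulina	universa	species		TRUE	Orbulina universa
Beella_digitata	Beella	digitata	species		TRUE	Beella digitata
Globigerinella_siphonifera	Globigerinella	siphonifera	species		TRUE	Globigerinella siphonifera
Globigerinella_calida	Globigerinella	calida	species		TRUE	Globigerinella calida
Globigerinella_adamsi	Globigerinella	adamsi	species		TRUE	Globigerinella adamsi
Turborotalita_quinqueloba	Turborotalita	quinqueloba	species		TRUE	Turborotalita quinqueloba
Turborotalita_humilis	Turborotalita	humilis	species		TRUE	Turborotalita humilis
Globoturborotalita_rubescens	Globoturborotalita	rubescens	species		TRUE	Globoturborotalita rubescens
Sphaeroidinella_dehiscens	Sphaeroidinella	dehiscens	species		TRUE	Sphaeroidinella dehiscens
Candeina_nitida	Candeina	nitida	species		TRUE	Candeina nitida
Globigerinita_glutinata	Globigerinita	glutinata	species		TRUE	Globigerinita glutinata
Globigerinita_uvula	Globigerinita	uvula	species		TRUE	Globigerinita uvula
Globigerinita_minuta	Globigerinita	minuta	species		TRUE	Globigerinita minuta
Tenuitella_iota	Tenuitella	iota	species		TRUE	Tenuitella iota
Hastigerina_pelagica	Hastigerina	pelagica	species		TRUE	Hastigerina pelagica
Hastigerinella_digitata	Hastigerinella	digitata	species		TRUE	Hastigerinella digitata
Globorotaloides_elongatus	Globorotaloides	elongatus	species		FALSE	Globorotaloides elongatus
Globigerinella_radians	Globigerinella	radians	species		FALSE	Globigerinella radians
Orcadia_riedeli	Orcadia	riedeli	species		FALSE	Orcadia riedeli
Turborotalita_clarkei	Turborotalita	clarkei	species		FALSE	Turborotalita clarkei
Tenuitella_fleisheri	Tenuitella	fleisheri	species		FALSE	Tenuitella fleisheri
Tenuitella_parkerae	Tenuitella	parkerae	species		FALSE	Tenuitella parkerae
Globorotalia_menardii_tumida	Globorotalia	menardii & tumida	multi_species		TRUE	Globorotalia menardii & Globorotalia tumida
Globigerinoides_ruber_pw	Globigerinoides	ruber (pink & white)	multi_species		TRUE	Globigerinoides ruber (pink) & Globigerinoides ruber (white)
Turborotalita_humilis_Berggrenia_pumilio	Turborotalita	humilis & Berggrenia pumilio	multi_species		TRUE	Turborotalita humilis & Berggrenia pumilio
Trilobatus_sacculifer_sac	Trilobatus	sacculifer (with sac)	morphotype	Trilobatus_sacculifer	TRUE	Trilobatus sacculifer with sac-like chamber
Trilobatus_sacculifer_wosac	Trilobatus	sacculifer (without sac)	morphotype	Trilobatus_sacculifer	TRUE	Trilobatus sacculifer without sac-like chamber
Globorotalia_truncatulinoides_dex	Globorotalia	truncatulinoides (dextral)	morphotype	Globorotalia_truncatulinoides	TRUE	Globorotalia truncatulinoides dextral
Globorotalia_truncatulinoides_sin	Globorotalia	truncatulinoides (sinistral)	morphotype	Globorotalia_truncatulinoides	TRUE	Globorotalia truncatulinoides sinistral
Turborotalita_quinqueloba_dex	Turborotalita	quinqueloba (dextral)	morphotype	Turborotalita_quinqueloba	TRUE	Turborotalita quinqueloba dextral
Turborotalita_quinqueloba_sin	Turborotalita	quinqueloba (sinistral)	morphotype	Turborotalita_quinqueloba	TRUE	Turborotalita quinqueloba sinistral
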