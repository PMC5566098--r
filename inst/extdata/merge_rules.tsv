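source_label	target	datasets	rationale
G. pachyderma	P/D intergrades	CLIMAP	CLIMAP's 'G. pachyderma' is interpreted as intermediate pachyderma/incompta morphologies, following its usage in the BUFD and ATL947 compilations
Globigerina pachyderma	P/D intergrades	CLIMAP	CLIMAP-scoped alias of the interpretation above
P/D intergrades	Neogloboquadrina_incompta	CLIMAP,ATL947,MARGO,MUNZ	intermediate pachyderma/incompta morphologies are assigned to N. incompta
G. flexuosa	Globorotalia_menardii	CLIMAP,BUFD	no evidence that the flexuosa morphotype is a separate species
Globorotalia flexuosa	Globorotalia_menardii	CLIMAP,BUFD	alias of the rule above
G. crassula	unidentified	BUFD,MARGO	extinct species whose morphology cannot be linked to an extant category
Globorotalia crassula	unidentified	BUFD,MARGO	alias of the rule above
other identified	unidentified	BUFD,MARGO	category carries no taxonomic information at the master resolution
G. puncticulata	Globoconella_inflata	MUNZ	extinct species with morphology overlapping its descendant G. inflata
Globorotalia puncticulata	Globoconella_inflata	MUNZ	alias of the rule above
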