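bit	value	label	description
1	1	CLIMAP	CLIMAP compilation
2	2	BUFD	Brown University Foraminiferal Database
3	4	ATL947	ATL947 database
4	8	MARGO North Atlantic	MARGO North Atlantic dataset
5	16	MARGO South Atlantic	MARGO South Atlantic dataset
6	32	MARGO Indo-Pacific	MARGO Indo-Pacific dataset
7	64	MARGO Pacific	MARGO Pacific dataset
8	128	MARGO Mediterranean	MARGO Mediterranean dataset
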