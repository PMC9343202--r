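pair_id	mirna_seq	cts_seq	label
pair_00001	CUUCGUGUUAUUAGUACGC	ACUAACGGUGGCACACGAAGG	1
pair_00002	GCCAACCGUUGAUUUUAAUAAUC	AACAUAAGCCGGUUGGCAGGCCUAUCCAG	1
pair_00003	CCCGAUGCCAACCUAAAAUGUGC	AUGGCAUCGGGGAGUAGAGACGUCGCGUA	1
pair_00004	UAGAAUAUGAGACUUAUUAAAA	UAAGGGCCCUCCCGGAGUACGU	0
pair_00005	GCACACAGGAUGCUGUACGGGGGCA	AACGGUCUGGAGGACCCGGCUGCGC	0
pair_00006	GUAACCCUUGGACUAACUAGA	AUGCCCGCCGUUUGGAUAGGGAGCGCU	0
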