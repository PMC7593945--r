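# synthetic CLASH-style tRF -> gene target map; toy data for tests
trf_id	gene_id
tRF-5003b	EIF6
tRF-5003b	PABPC1
tRF-5003b	WARS
tRF-5003b	RPS6KB1
tRF-5003b	EIF4EBP2
tRF-5003b	RICTOR
tRF-5003b	MAPK1
tRF-5003b	QARS
tRF-5003b	KARS
tRF-5003b	AIMP1
tRF-3021a	ARAF
tRF-3021a	MAPK3
tRF-3021a	EPRS
tRF-3021a	MARS
tRF-3021a	EIF4E
tRF-3021a	RPS28
tRF-3021a	TGFBI
tRF-3021a	IARS
tRF-3021a	EIF2S1
tRF-3021a	RAPTOR
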