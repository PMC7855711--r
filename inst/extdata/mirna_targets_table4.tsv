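mirna_id	mrna_id	source_db
miR-30a-5p	DSP	TarBase_v8
miR-30a-5p	PLS1	TarBase_v8
miR-30a-5p	TPD52	TarBase_v8
miR-205-3p	PRKAA1	TarBase_v8
miR-302c-3p	ARL4A	TarBase_v8
miR-302c-3p	VDR	TarBase_v8
miR-330-5p	ACVR1B	TarBase_v8
miR-330-5p	CC2D1A	TarBase_v8
miR-330-5p	HIGD2A	TarBase_v8
miR-330-5p	RNF43	TarBase_v8
miR-330-5p	ZDHHC9	TarBase_v8
miR511-5p	SH3YL1	TarBase_v8
miR511-5p	USP7	TarBase_v8
miR-544a	CD9	TarBase_v8
miR-544a	DSP	TarBase_v8
miR-544a	EPCAM	TarBase_v8
miR-544a	GALNT3	TarBase_v8
miR-544a	MIER3	TarBase_v8
miR-1231	CTNNA1	TarBase_v8
miR-1231	EIF6	TarBase_v8
miR-3619-5p	ACVR1B	TarBase_v8
miR-3619-5p	ADD3	TarBase_v8
miR-3619-5p	SRPK1	TarBase_v8
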