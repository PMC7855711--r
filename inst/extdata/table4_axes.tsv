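mirna_id	mirna_cancer_direction	mrna_id	r_mirna_mrna	p_mirna_mrna	r_lnc_mrna	p_lnc_mrna	note
miR-30a-5p	Downregulated	DSP	-0.11	2.00e-02	0.406	2.68e-12	NA
miR-30a-5p	Downregulated	PLS1	-0.185	7.57e-05	0.569	7.92e-26	NA
miR-30a-5p	Downregulated	TPD52	-0.271	5.39e-09	0.428	1.02e-13	NA
miR-205-3p	Downregulated	PRKAA1	-0.098	3.81e-02	0.207	2.27e-04	NA
miR-302c-3p	Downregulated	ARL4A	-0.087	6.47e-02	0.471	7.75e-17	NA
miR-302c-3p	Downregulated	VDR	-0.072	1.25e-01	0.559	1.61e-30	NA
miR-330-5p	Downregulated	ACVR1B	-0.106	2.47e-02	0.442	1.14e-04	NA
miR-330-5p	Downregulated	CC2D1A	-0.206	1.09e-05	0.32	1.02e-07	NA
miR-330-5p	Downregulated	HIGD2A	-0.158	7.55e-04	0.363	5.07e-12	NA
miR-330-5p	Downregulated	RNF43	-0.238	3.37e-07	0.451	2.56e-15	NA
miR-330-5p	Downregulated	ZDHHC9	-0.102	2.98e-02	0.389	3.10e-11	NA
miR511-5p	Downregulated	SH3YL1	-0.084	6.27e-01	0.349	NA	p_lnc_mrna truncated in source
miR511-5p	Downregulated	USP7	-0.122	9.56e-03	0.372	2.78e-10	NA
miR-544a	Upregulated	CD9	0.014	7.73e-01	0.391	1.89e-10	NA
miR-544a	Upregulated	DSP	-0.007	8.80e-01	0.406	2.68e-12	NA
miR-544a	Upregulated	EPCAM	-0.019	6.95e-01	0.479	1.92e-17	NA
miR-544a	Upregulated	GALNT3	0.041	3.84e-01	0.422	2.66e-13	NA
miR-544a	Upregulated	MIER3	0.015	7.46e-01	0.376	1.53e-10	NA
miR-1231	NA	CTNNA1	-0.238	3.21e-07	0.321	2.00e-09	NA
miR-1231	NA	EIF6	-0.045	3.45e-01	0.44	1.68e-14	NA
miR-3619-5p	NA	ACVR1B	-0.133	4.64e-03	0.442	1.14e-04	NA
miR-3619-5p	NA	ADD3	-0.02	6.76e-01	0.437	1.10e-17	NA
miR-3619-5p	NA	SRPK1	-0.063	1.81e-01	0.38	1.00e-10	NA
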