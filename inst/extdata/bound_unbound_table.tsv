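protein	bound_id	free_id	identity	class	p_bound	p_free	Q1_bound	Q1_free
30S Ribosomal protein S15	1fjgO	2fkxA	100	rRNA	4.37	4.44	5.77	7.36
30S Ribosomal protein S6	1fjgF	1louA	99	rRNA	2.34	2.66	7.90	8.74
30S Ribosomal protein S7	1fjgG	1rssA	100	rRNA	4.95	3.30	22.12	9.56
30S Ribosomal protein S19	1ibmS	1qkfA	100	rRNA	5.04	3.83	12.96	8.43
30S Ribosomal protein S16	1hnwP	1emwA	100	rRNA	4.27	4.31	7.22	6.76
Ribosomal protein L11	1hc8A	2f0wA	100	rRNA	1.79	1.84	6.64	6.41
Ribosomal protein L25	1d6kA	1b75A	100	rRNA	3.59	3.35	10.26	9.90
60S Ribosomal protein L30	1cn8A	1cn7A	100	rRNA	2.94	2.41	4.61	4.97
Glutaminyl-tRNA synthetase	1euyA	1nylA	98	tRNA	1.10	1.15	14.24	15.46
Queuine tRNA-ribosyltransferase	1q2rA	1r5yA	100	tRNA	2.19	2.26	2.83	3.75
Glutamyl-tRNA synthetase	1g59A	1j09A	99	tRNA	1.64	1.50	13.21	13.77
Aspartyl tRNA-synthetase	1asyA	1eovA	100	tRNA	4.03	5.06	7.48	9.39
Elongation factor TU	1b23P	2c78A	98	tRNA	3.62	3.44	12.65	11.21
Arginyl tRNA synthetase	1f7uA	1bs2A	100	tRNA	2.22	2.31	12.44	13.83
Small protein B	1p6vA	1k8hA	98	tRNA	0.69	1.71	16.40	18.62
Pseudouridine synthase B	1k8wA	1r3fA	100	tRNA	1.65	1.90	18.31	17.41
Tyrosyl tRNA synthetase	1j1uA	2ag6A	96	tRNA	1.34	1.75	16.60	15.22
Bacteriophage coat protein MS2	1aq3A	1mscA	98	viral	2.08	2.08	4.77	3.65
Minor core protein lambda 3	1n1hA	1mukA	100	viral	1.65	1.42	11.95	12.44
RNA polymerase HC-J4	1nb7A	1gx5A	96	viral	3.81	2.77	12.44	10.34
HIV-I nucleocapsid protein	1a1tA	1mfsA	100	viral	4.24	3.65	12.74	23.69
NHP2-like protein 1	1e7kA	2jnbA	100	other	3.27	5.06	4.28	8.61
Spliceosomal U1A protein	1audA	1fhtA	98	other	1.36	2.60	7.93	12.88
Pumilio homology domain	1m8yB	1m8zA	100	other	4.00	4.05	20.01	20.46
Rho transcription termination factor	2a8vA	1a62A	NA	other	1.84	1.86	12.42	10.87
Transcription factor IIIA	1un6B	2j7jA	100	other	3.92	1.94	16.83	30.18
VP39 protein	1av6A	4dcgA	98	other	3.18	3.09	6.53	6.25
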