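protein_id	q1_mz	start	end	peptide	rt_min	fc_1	p_1	fc_10	p_10
CPS1_HUMAN	663.36	275	286	GQNQPVLNITNK	6.7	1.73	0.0001	1.74	0.0003
CPS1_HUMAN	804.4	491	505	VLGTSVESIMATEDR	9.58	1.77	0.0013	1.84	0.0008
CPS1_HUMAN	795.43	519	533	IAPSFAVESIEDALK	12.45	2.57	0.0338	2.4	0.0473
CPS1_HUMAN	653.85	534	545	AADTIGYPVMIR	9.13	1.3	0.0016	1.25	0.0033
CPS1_HUMAN	582.37	699	709	IALGIPLPEIK	11.24	1.23	0.0179	1.2	0.0422
CPS1_HUMAN	615.83	1033	1043	IMGTSPLQIDR	8.04	1.44	0.0011	1.41	0.0013
CPS1_HUMAN	611.34	1048	1058	SIFSAVLDELK	13.44	1.88	0.0001	1.85	0.0001
CPS1_HUMAN	433.22	1109	1115	FLEEATR	5.05	1.34	0.0235	1.28	0.0315
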