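protein_id	set_name	residue_letter	residue_index
CPS1_HUMAN	L1_ADP_site	T	502
CPS1_HUMAN	L1_ADP_site	E	503
CPS1_HUMAN	L1_ADP_site	R	505
CPS1_HUMAN	L1_ADP_site	M	543
CPS1_HUMAN	L1_ADP_site	R	545
CPS1_HUMAN	L1_ADP_site	E	581
CPS1_HUMAN	L1_ADP_site	K	582
CPS1_HUMAN	L1_ADP_site	V	584
CPS1_HUMAN	L1_ADP_site	E	589
CPS1_HUMAN	L1_ADP_site	M	614
CPS1_HUMAN	L1_ADP_site	H	617
CPS1_HUMAN	L1_ADP_site	Q	658
CPS1_HUMAN	L1_ADP_site	E	672
CPS1_HUMAN	L1_ADP_site	N	674
CPS1_HUMAN	L1_ADP_site	R	676
CPS1_HUMAN	L1_ADP_site	R	679
CPS1_HUMAN	L3_ADP_site	R	1087
CPS1_HUMAN	L3_ADP_site	K	1126
CPS1_HUMAN	L3_ADP_site	V	1128
CPS1_HUMAN	L3_ADP_site	E	1133
CPS1_HUMAN	L3_ADP_site	H	1160
CPS1_HUMAN	L3_ADP_site	Q	1201
CPS1_HUMAN	L3_ADP_site	E	1213
CPS1_HUMAN	L3_ADP_site	R	1217
CPS1_HUMAN	L3_ADP_site	R	1220
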