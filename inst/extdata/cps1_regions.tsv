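protein_id	name	start	end	category
CPS1_HUMAN	S1	1	212	domain
CPS1_HUMAN	S2	213	400	domain
CPS1_HUMAN	L1	401	744	domain
CPS1_HUMAN	L2	745	1030	domain
CPS1_HUMAN	L3	1031	1268	domain
CPS1_HUMAN	T'-loop	1269	1291	loop
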