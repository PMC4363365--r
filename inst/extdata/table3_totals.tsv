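group	N_total	M_total	I_total
BC	1610	2.70	50.30
BBP	1932	4.83	95.52
H	1642	3.63	67.32
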