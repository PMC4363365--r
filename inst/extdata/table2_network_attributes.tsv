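attribute	H	BBP	BC
n_nodes	121	121	121
n_links	1642	1932	1610
diameter	7	6	7
density	0.06	0.07	0.06
top_node	24	115	111
degree_min	2	2	2
degree_max	39	45	32
degree_mean	13.57	15.93	13.28
degree_sd	7.23	9.56	6.68
degree_var	52.26	91.35	44.59
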