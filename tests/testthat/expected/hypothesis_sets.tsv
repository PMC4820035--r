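set_id	n_genes	P	P_minus_best	P_del	P_dup	P_dup_vs_del	beta_hit	n_case_hits	n_control_hits	P_bonferroni
TARGET	18	0.0470749	0.147665	0.0518124	0.335838	0.724406	0.544966	88	60	0.188299
BG1	25	0.258053	0.701875	0.431608	0.41569	0.997714	-0.301785	72	68	1
BG2	12	0.655578	0.759512	0.173541	0.595903	0.172828	0.117512	51	39	1
TINY	2	0.295947	0.994427	0.0474777	0.61387	0.23921	-0.537963	7	10	1
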