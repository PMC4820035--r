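set_id	n_genes	n_hits	lrt_stat	p_value	beta_hit	n_case_hits	n_control_hits	q_value
TARGET	18	203	3.94271	0.0470749	0.544966	88	60	0.0941497
BG1	25	210	1.27917	0.258053	-0.301785	72	68	0.258053
BG2	12	113	0.19894	0.655578	0.117512	51	39	0.437052
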