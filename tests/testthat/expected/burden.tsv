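study_id	stratum	n_case_cnvs	n_control_cnvs	case_rate	control_rate	ratio	p_value
ALPHA	ALL	48	38	0.8	0.422222	1.89474	0.00435593
BETA	ALL	51	45	0.6375	0.45	1.41667	0.10846
GAMMA	ALL	45	35	0.9	0.5	1.8	0.0119733
ALPHA	DEL	27	16	0.45	0.177778	2.53125	0.00422697
BETA	DEL	18	14	0.225	0.14	1.60714	0.244099
GAMMA	DEL	25	20	0.5	0.285714	1.75	0.0839178
ALPHA	DUP	21	22	0.35	0.244444	1.43182	0.30445
BETA	DUP	33	31	0.4125	0.31	1.33065	0.307685
GAMMA	DUP	20	15	0.4	0.214286	1.86667	0.0937813
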