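cycle	h2o2_mmol_l	passages	generations	lag_start_h	lag_end_h	mu_max_start_h	mu_max_end_h
1	10	16	30	46	4	0.027	0.045
2	20	15	20	30	5	0.045	0.055
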