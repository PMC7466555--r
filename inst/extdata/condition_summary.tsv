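quantity	REF	LIG	PER	ADA
carotenoid_titre_mg_l	20.7	36.2	19.3	44.0
carotenoid_yield_mg_gdcw	0.85	1.45	0.89	1.90
carotenoid_q_mg_l_h	0.12	0.22	0.06	0.23
carotenoid_yield_substrate_mg_g	0.29	0.54	0.29	0.62
lipid_titre_g_l	8.1	11.1	13.8	13.3
lipid_yield_g_gdcw	0.33	0.46	0.65	0.58
lipid_q_g_l_h	0.05	0.07	0.05	0.07
lipid_yield_substrate_g_g	0.12	0.17	0.21	0.19
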