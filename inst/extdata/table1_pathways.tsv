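pathway	step	label	substrate_mM	carrier_mM	K_mM	flux_mM_per_s
ecoli-glycolysis	consuming	PFK	0.0321	0.828	0.16	1.44
ecoli-glycolysis	producing	PK	0.149	0.965	0.26	1.44
llactis-fermentation	consuming	GAPDH	6.0	8.4	0.2	5.0
llactis-fermentation	producing	LDH	1.0	0.7	0.08	4.4
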