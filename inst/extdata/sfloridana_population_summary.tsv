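county	population	sites	N	H_E	H_O	F_IS	divergence	unique_ancestry	genetic_value
Bay	LB1	1	23	0.142	0.125	0.113	Moderate	Yes	Moderate
Franklin	ANF1	1	19	0.125	0.106	0.137	Moderate	Yes	Moderate
Franklin	ANF2	1	14	0.128	0.127	0.024	Very High	Yes	High
Franklin	BRWMA1	1	10	0.139	0.04	0.555	Moderate	No	Low
Franklin	BRWMA2	1	11	0.136	0.139	-0.01	Very High	Yes	High
Franklin	THSF1	1	14	0.131	0.081	0.297	Moderate	No	Low
Franklin	THSF2	2	18	0.131	0.13	0.025	High	Yes	High
Gulf	SJSBP1	2	7	0.145	0.090	0.268	Moderate	No	Low
Gulf	SJSBP2	1	12	0.145	0.136	0.060	Moderate	Yes	Moderate
Liberty	ANF3	1	18	0.126	0.132	-0.02	Very High	Yes	High
Liberty	ANF4	3	34	0.138	0.116	0.154	Low	Yes	Moderate
Liberty	ANF5	2	11	0.124	0.044	0.504	Moderate	No	Low
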