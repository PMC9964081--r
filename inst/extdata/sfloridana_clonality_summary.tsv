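population	N	threshold	G	ramets	CR
ANF1	19	0.01	16	4,1(15)	0.83
ANF2	14	NA	14	1(14)	1.00
ANF3	18	0.02	15	3,2,1(13)	0.82
ANF4.1	7	0.01	5	3,1(4)	0.67
ANF4.2	15	0.01	11	5,1(10)	0.71
ANF4.3	11	NA	11	1(11)	1.00
ANF5	11	0.02	1	11(1)	0
BRWMA1	10	0.002	3	8,1(2)	0.22
BRWMA2	11	0.02	8	3,2,1(6)	0.70
LB1	23	0.02	3	18,3,2	0.09
SJSBP1	7	0.01	4	4,1(3)	0.50
SJSBP2	12	0.03	10	2,2,1(8)	0.82
THSF1	14	0.03	2	13,1	0.08
THSF2	18	0.01	14	3,2,2,1(11)	0.76
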