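run	BA#	EO#	LY	LY#	MCH	MCHC	MO	MO#	MPV	PDW	PLT	RBC	RDW	WBC	sn_ratio
1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	8.29
2	1	1	1	1	1	1	1	2	2	2	2	2	2	2	3.36
3	1	1	1	2	2	2	2	1	1	1	1	2	2	2	8.38
4	1	1	1	2	2	2	2	2	2	2	2	1	1	1	3.10
5	1	2	2	1	1	2	2	1	1	2	2	1	1	2	2.94
6	1	2	2	1	1	2	2	2	2	1	1	2	2	1	7.87
7	1	2	2	2	2	1	1	1	1	2	2	2	2	1	2.98
8	1	2	2	2	2	1	1	2	2	1	1	1	1	2	7.16
9	2	1	2	1	2	1	2	1	2	1	2	1	2	1	8.40
10	2	1	2	1	2	1	2	2	1	2	1	2	1	2	3.54
11	2	1	2	2	1	2	1	1	2	1	2	2	1	2	7.34
12	2	1	2	2	1	2	1	2	1	2	1	1	2	1	3.70
13	2	2	1	1	2	2	1	1	2	2	1	1	2	2	2.10
14	2	2	1	1	2	2	1	2	1	1	2	2	1	1	9.36
15	2	2	1	2	1	1	2	1	2	2	1	2	1	1	2.72
16	2	2	1	2	1	1	2	2	1	1	2	1	2	2	8.50
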