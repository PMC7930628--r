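simulated_cr	tested_cr	af_design	TP	TN	FP	FN
2	2	100	32	16533	0	4
10	2	100	32	16507	26	4
10	10	100	32	16532	1	4
20	23	100	32	16529	4	4
30	27	100	32	16476	57	4
40	38	100	32	16478	55	4
2	2	30	31	16533	0	5
10	2	30	32	16510	23	4
10	10	30	31	16528	5	5
20	2	30	31	16458	75	5
20	20	30	30	16499	34	6
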