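sample	TP	TN	FP	FN
Pol-1	34	16528	1	6
Pol-2	30	16534	1	4
Pol-3	26	16536	2	5
Pol-4	8	16557	0	4
Pol-5	8	16559	0	2
Pol-6	34	16531	1	3
Pol-7	33	16534	0	2
Pol-9	25	16542	0	2
Pol-10	11	16553	1	4
Pol-11	35	16527	0	7
Pol-12	32	16533	1	3
Pol-13	11	16556	0	2
Pol-14	7	16560	0	2
Pol-15	13	16553	0	3
Pol-16	18	16547	0	4
Pol-17	25	16536	1	7
Pol-18	26	16535	2	6
Pol-21	23	16539	1	6
Pol-22	8	16555	3	3
Pol-23	30	16534	0	5
Pol-24	11	16554	1	3
Pol-25	8	16556	0	5
Pol-26	30	16536	0	3
Pol-27	28	16538	1	2
Pol-28	10	16557	0	2
Pol-29	8	16556	0	5
Pol-30	19	16547	0	3
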