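start	end	name	biotype
16024	576	D-loop	D-loop
577	647	MT-TF	tRNA
648	1601	MT-RNR1	rRNA
1602	1670	MT-TV	tRNA
1671	3229	MT-RNR2	rRNA
3230	3304	MT-TL1	tRNA
3305	3306	IG1	intergenic
3307	4262	MT-ND1	protein_coding
4263	4331	MT-TI	tRNA
4332	4400	MT-TQ	tRNA
4401	4402	IG2	intergenic
4403	4469	MT-TM	tRNA
4470	5511	MT-ND2	protein_coding
5512	5579	MT-TW	tRNA
5580	5655	MT-TA	tRNA
5656	5729	MT-TN	tRNA
5730	5760	OL	intergenic
5761	5826	MT-TC	tRNA
5827	5891	MT-TY	tRNA
5892	5903	IG3	intergenic
5904	7445	MT-CO1	protein_coding
7446	7514	MT-TS1	tRNA
7515	7517	IG4	intergenic
7518	7585	MT-TD	tRNA
7586	8269	MT-CO2	protein_coding
8270	8294	IG5	intergenic
8295	8364	MT-TK	tRNA
8365	8572	MT-ATP8	protein_coding
8573	9207	MT-ATP6	protein_coding
9208	9990	MT-CO3	protein_coding
9991	10058	MT-TG	tRNA
10059	10404	MT-ND3	protein_coding
10405	10469	MT-TR	tRNA
10470	10766	MT-ND4L	protein_coding
10767	12137	MT-ND4	protein_coding
12138	12206	MT-TH	tRNA
12207	12265	MT-TS2	tRNA
12266	12336	MT-TL2	tRNA
12337	14148	MT-ND5	protein_coding
14149	14673	MT-ND6	protein_coding
14674	14742	MT-TE	tRNA
14743	14746	IG6	intergenic
14747	15887	MT-CYB	protein_coding
15888	15953	MT-TT	tRNA
15954	15955	IG7	intergenic
15956	16023	MT-TP	tRNA
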