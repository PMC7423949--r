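chrom	class	length_bp	n_genes	genes_per_mbp_printed
1	AUTOSOME	158534110	1216	7.67
2	AUTOSOME	136231102	1284	9.43
3	AUTOSOME	121005158	1287	10.64
4	AUTOSOME	120000601	593	4.94
5	AUTOSOME	120089316	1080	8.99
6	AUTOSOME	117806340	692	5.87
7	AUTOSOME	110682743	1264	11.42
8	AUTOSOME	113319770	898	7.92
9	AUTOSOME	105454467	800	7.59
10	AUTOSOME	103308737	1554	15.04
11	AUTOSOME	106982474	1620	15.14
12	AUTOSOME	87216183	1194	13.69
13	AUTOSOME	83472345	479	5.74
14	AUTOSOME	82403003	864	10.49
15	AUTOSOME	85007780	738	8.68
16	AUTOSOME	81013979	1127	13.91
17	AUTOSOME	73167244	446	6.10
18	AUTOSOME	65820629	948	14.40
19	AUTOSOME	63449741	526	8.29
20	AUTOSOME	71974595	387	5.38
21	AUTOSOME	69862954	412	5.90
22	AUTOSOME	60773035	845	13.90
23	AUTOSOME	52498615	1708	32.53
24	AUTOSOME	62317253	1048	16.82
25	AUTOSOME	42350435	1611	38.04
26	AUTOSOME	51992305	849	16.33
27	AUTOSOME	45612108	1665	36.50
28	AUTOSOME	45940150	982	21.38
29	AUTOSOME	51098607	733	14.34
X	X	139009144	1222	8.79
Y	Y	43300181	206	4.76
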