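chrom	size_mbp	genes	ggrs	chip60k	chip600k	d_genes	d_ggrs	d_chip60k	d_chip600k
1	195.28	2798	19171	8517	102501	14.33	98.17	43.61	524.89
2	148.81	1926	12549	6460	64755	12.94	84.33	43.41	435.15
3	110.45	1549	8761	4900	57517	14.02	79.32	44.36	520.75
4	90.22	1475	7513	3966	43569	16.35	83.27	43.96	482.92
5	59.58	1191	5097	2598	30907	19.99	85.55	43.61	518.75
6	34.95	640	3230	2042	22055	18.31	92.42	58.43	631.04
7	36.24	653	2822	2134	21792	18.02	77.87	58.89	601.32
8	28.77	633	2814	1679	17334	22	97.81	58.36	602.5
9	23.44	532	2114	1403	18236	22.7	90.19	59.85	777.99
10	19.91	515	1888	1570	19046	25.87	94.83	78.85	956.6
11	19.4	442	1461	1519	14021	22.78	75.31	78.3	722.73
12	19.9	407	2095	1614	14918	20.45	105.28	81.11	749.65
13	17.76	441	2383	1385	11373	24.83	134.18	77.98	640.37
14	15.16	487	2259	1197	13246	32.12	149.01	78.96	873.75
15	12.66	430	1377	1235	10542	33.97	108.77	97.55	832.7
16	0.53527	86	491	29	602	160.67	917.29	54.18	1124.67
17	10.45	376	1939	1023	9494	35.98	185.55	97.89	908.52
18	11.22	377	1653	1077	10063	33.6	147.33	95.99	896.88
19	9.98	383	1213	993	9123	38.38	121.54	99.5	914.13
20	14.3	443	1840	1840	9786	30.98	128.67	128.67	684.34
21	6.8	286	1057	902	8988	42.06	155.44	132.65	1321.76
22	4.08	147	407	463	4727	36.03	99.75	113.48	1158.58
23	5.72	268	861	751	6734	46.85	150.52	131.29	1177.27
24	6.32	214	937	869	7820	33.86	148.26	137.5	1237.34
25	2.19	255	579	235	2690	116.44	264.38	107.31	1228.31
26	5.33	279	1276	815	6446	52.35	239.4	152.91	1209.38
27	5.21	334	1296	590	5804	64.11	248.75	113.24	1114.01
28	4.74	299	948	777	5589	63.08	200	163.92	1179.11
Z	82.36	1146	1286	3010	26038	13.91	15.61	36.55	316.15
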