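min_score	dm0_target	dm0_decoy	dmneg_target	dmneg_decoy	dmpos_target	dmpos_decoy	total_target	total_decoy	fdr_pct
7	14207	17401	145801	86218	122479	69298	282487	172917	37.97
9	5132	4787	145756	86183	122465	69287	273353	160257	36.96
11	1944	1793	144795	85247	121833	68671	268572	155711	36.71
13	721	343	139895	80327	119006	65901	259622	146571	36.08
15	496	187	116674	61154	110457	58923	227627	120264	34.57
17	341	42	58584	13053	55297	13052	114222	26147	18.63
19	250	36	37840	1681	35439	1647	73529	3364	4.37
21	201	12	29675	271	27908	251	57784	534	0.92
23	160	10	24262	87	22881	82	47303	179	0.38
25	131	5	20036	35	18910	36	39077	76	0.19
27	108	4	16686	18	15792	14	32586	36	0.11
29	92	2	13835	12	13120	9	27047	23	0.08
31	67	2	11345	4	10801	5	22213	11	0.05
33	54	0	9314	2	8888	3	18256	5	0.03
35	44	0	7608	2	7296	2	14948	4	0.03
37	39	0	6231	2	5989	2	12259	4	0.03
39	17	0	5008	1	4832	1	9857	2	0.02
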