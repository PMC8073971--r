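min_score	dm0_target	dm0_decoy	dmneg_target	dmneg_decoy	dmpos_target	dmpos_decoy	total_target	total_decoy	fdr_pct
7	71852	87705	88895	39432	107842	59678	268589	186815	41.02
8	71852	87705	55874	12352	61225	19550	188951	119607	38.76
9	32972	32740	41378	3874	40085	4822	114435	41436	26.58
10	32970	32739	31973	868	30245	1026	95188	34633	26.68
11	10918	11209	26095	310	24547	305	61560	11824	16.11
12	10918	11208	21553	112	20313	94	52784	11414	17.78
13	2571	1180	17893	46	16939	34	37403	1260	3.26
14	2571	1180	14955	22	14243	17	31769	1219	3.71
15	1137	380	12352	9	11818	9	25307	398	1.55
16	1137	380	10239	6	9801	5	21177	391	1.81
17	672	61	8403	5	8085	4	17160	70	0.41
18	672	61	6907	4	6662	3	14241	68	0.48
19	495	49	5590	2	5413	1	11498	52	0.45
20	495	49	4557	1	4415	1	9467	51	0.54
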