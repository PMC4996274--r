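sample_id	clone_id	donor_age	barcode	expression	frag1_meth	frag1_unmeth	frag1_ratio	frag2_meth	frag2_unmeth	frag2_ratio
BMA01	BMA01-C13	73	ATATCTCAA	0	315	2175	0.145	106	4706	0.023
BMA01	BMA01-C14	73	ACTAGGTCC	0	726	1922	0.378	185	4220	0.044
BMA01	BMA01-C2	73	CCACGGCCG	0	494	1173	0.421	63	1907	0.033
BMA01	BMA01-C3	73	TCCTTAGCT	0	2829	8051	0.351	198	3721	0.053
BMA01	BMA01-C4	73	GAGACGTAA	0	2945	13298	0.221	483	2891	0.167
BMA01	BMA01-C8	73	GTTATGTAT	0	1400	2578	0.543	289	3385	0.085
BMA01	BMA01-C1	73	GTTTACAGT	1	2807	8399	0.334	1118	5777	0.194
BMA01	BMA01-C11	73	CAATCCCTC	1	299	1710	0.175	65	2599	0.025
BMA01	BMA01-C5	73	ACGGCCCTA	1	1292	5065	0.255	500	9305	0.054
BMA01	BMA01-C7	73	TTGCTAGGT	1	1548	7087	0.218	1634	6205	0.263
BMA02	BMA02-T1C1	42	GAGTAGGCA	0	2810	3381	0.831	139	2570	0.054
BMA02	BMA02-T1C4	42	TACGCTGGA	0	855	978	0.874	290	1092	0.266
BMA02	BMA02-T1C6	42	GGGCCATTG	0	171	439	0.39	20	374	0.053
BMA02	BMA02-T1C8	42	CGTGTACGC	0	254	801	0.317	47	846	0.056
BMA02	BMA02-T2C7	42	GACACCGGT	0	3751	3841	0.977	60	1346	0.045
BMA02	BMA02-T2C8	42	ACCAACCTT	0	3883	3968	0.979	52	1153	0.045
BMA02	BMA02-T3C8	42	TACAGGTTT	0	805	2976	0.27	147	2172	0.068
BMA02	BMA02-T1C12	42	GTACTCATG	1	297	4544	0.065	93	2114	0.044
BMA02	BMA02-T1C9	42	ACTCCGAGT	1	225	779	0.289	45	750	0.06
BMA03	BMA03-T1C1	47	TCTCCACAG	0	928	7605	0.122	137	4139	0.033
BMA03	BMA03-T2C1	47	TGAGCATGG	0	1301	6712	0.194	175	5350	0.033
BMA03	BMA03-T2C4	47	CAGAGTGTT	0	830	6879	0.121	80	3174	0.025
BMA03	BMA03-T2C5	47	AACCGCGTT	0	1354	7333	0.185	48	2573	0.019
BMA03	BMA03-T2C9	47	TCTAATGTT	0	844	4334	0.195	172	3073	0.056
BMA03	BMA03-T1C5	47	AACCCAAGA	1	1224	5789	0.211	113	3275	0.035
BMA03	BMA03-T2C7	47	TCCTTCTGG	1	6301	13041	0.483	166	2503	0.066
BMA04	BMA04-C13	74	GTAGCCTCG	0	2233	6501	0.343	516	3064	0.168
BMA04	BMA04-C14	74	AATGGCTTA	0	11820	37208	0.318	387	2595	0.149
BMA04	BMA04-C6	74	TGCCGGATA	1	1609	5991	0.269	429	2590	0.166
BMA04	BMA04-C7	74	CCCAAGGTG	1	2063	5976	0.345	474	2787	0.17
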