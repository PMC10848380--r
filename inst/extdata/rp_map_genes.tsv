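entrez_id	symbol	source
1258	CNGB1	core
23568	ARL2BP	core
1259	CNGA1	core
23020	SNRNP200	core
2563	GABRD	hpo_amplified
55624	POMGNT1	core
2697	GJA1	hpo_amplified
5995	RGR	core
2969	GTF2I	hpo_amplified
26160	IFT172	core
3845	KRAS	hpo_amplified
403	ARL3	core
3984	LIMK1	hpo_amplified
10461	MERTK	core
9569	GTF2IRD1	hpo_amplified
23404	EXOSC2	core
51684	SUFU	hpo_amplified
9128	PRPF4	core
64218	SEMA4A	core
6102	RP2	core
4751	NEK2	core
50939	IMPG2	core
9227	LRAT	core
28982	FLVCR1	core
5949	RBP3	core
5148	PDE6G	core
6010	RHO	core
6103	RPGR	core
9742	IFT140	core
123016	TTC8	core
7399	USH2A	core
55812	SPATA7	core
60509	AGBL5	core
3614	IMPDH1	core
6121	RPE65	core
7287	TULP1	core
138050	HGSNAT	core
10210	TOPORS	core
6101	RP1	core
6295	SAG	core
57709	SLC7A14	core
10283	CWC27	core
5158	PDE6B	core
23746	AIPL1	core
26090	ABHD12	core
1406	CRX	core
112752	IFT43	core
6094	ROM1	core
375298	CERKL	core
5145	PDE6A	core
10594	PRPF8	core
92211	CDHR1	core
10083	USH1C	core
3420	IDH3B	core
4647	MYO7A	core
84140	FAM161A	core
6100	RP9	core
5961	PRPH2	core
3098	HK1	core
130557	ZNF513	core
7401	CLRN1	core
25794	FSCN2	core
92840	REEP6	core
80025	PANK2	core
23370	ARHGEF18	core
51095	TRNT1	core
8481	OFD1	core
768206	PRCD	core
346007	EYS	core
388939	PCARE	core
4117	MAK	core
6017	RLBP1	core
196	AHR	core
8842	PROM1	core
23418	CRB1	core
7439	BEST1	core
9785	DHX38	core
54806	AHI1	core
79797	ZNF408	core
8100	IFT88	core
79947	DHDDS	core
4901	NRL	core
49855	SCAPER	core
55975	KLHL7	core
24	ABCA4	core
9129	PRPF3	core
2677	GGCX	core
57670	KIAA1549	core
26121	PRPF31	core
583	BBS2	core
84100	ARL6	core
145226	RDH12	core
55857	KIZ	core
3419	IDH3A	core
24148	PRPF6	core
7275	TUB	core
2979	GUCA1B	core
762	CA4	core
10002	NR2E3	core
4508	ATP6	core
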