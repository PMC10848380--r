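disease_id	entrez_id	symbol
OMIM:615565	4751	NEK2
OMIM:616394	26160	IFT172
OMIM:613341	9227	LRAT
OMIM:618173	403	ARL3
OMIM:615233	5949	RBP3
OMIM:613862	10461	MERTK
OMIM:613731	6010	RHO
OMIM:617763	23404	EXOSC2
OMIM:613767	1258	CNGB1
OMIM:615922	9128	PRPF4
OMIM:617781	9742	IFT140
OMIM:312600	6102	RP2
OMIM:613809	7399	USH2A
OMIM:613581	50939	IMPG2
OMIM:617023	60509	AGBL5
OMIM:609033	28982	FLVCR1
OMIM:613794	6121	RPE65
OMIM:613582	5148	PDE6G
OMIM:616544	138050	HGSNAT
OMIM:300029	6103	RPGR
OMIM:180100	6101	RP1
OMIM:613464	123016	TTC8
OMIM:615725	57709	SLC7A14
OMIM:604232	55812	SPATA7
OMIM:613801	5158	PDE6B
OMIM:180105	3614	IMPDH1
OMIM:612674	26090	ABHD12
OMIM:600132	7287	TULP1
OMIM:617871	112752	IFT43
OMIM:609923	10210	TOPORS
OMIM:608380	375298	CERKL
OMIM:613758	6295	SAG
OMIM:600059	10594	PRPF8
OMIM:250410	10283	CWC27
OMIM:276900	10083	USH1C
OMIM:268000	23746	AIPL1
OMIM:276900	4647	MYO7A
OMIM:268000	1259	CNGA1
OMIM:180104	6100	RP9
OMIM:268000	1406	CRX
OMIM:617460	3098	HK1
OMIM:268000	6094	ROM1
OMIM:614180	7401	CLRN1
OMIM:613810	5145	PDE6A
OMIM:617304	92840	REEP6
OMIM:613660	92211	CDHR1
OMIM:617433	23370	ARHGEF18
OMIM:612572	3420	IDH3B
OMIM:300424	8481	OFD1
OMIM:606068	84140	FAM161A
OMIM:602772	346007	EYS
OMIM:608133	5961	PRPH2
OMIM:614181	4117	MAK
OMIM:613617	130557	ZNF513
OMIM:618345	196	AHR
OMIM:607921	25794	FSCN2
OMIM:600105	23418	CRB1
OMIM:607236	80025	PANK2
OMIM:610282	64218	SEMA4A
OMIM:616959	51095	TRNT1
OMIM:618220	9785	DHX38
OMIM:610599	768206	PRCD
OMIM:616469	79797	ZNF408
ORPHA:436274	2677	GGCX
OMIM:613861	79947	DHDDS
ORPHA:791	6017	RLBP1
OMIM:618195	49855	SCAPER
ORPHA:791	8842	PROM1
OMIM:601718	24	ABCA4
ORPHA:791	7439	BEST1
OMIM:613428	388939	PCARE
ORPHA:791	54806	AHI1
OMIM:600138	26121	PRPF31
ORPHA:791	8100	IFT88
OMIM:613575	84100	ARL6
ORPHA:791	4901	NRL
OMIM:615780	55857	KIZ
ORPHA:791	55975	KLHL7
OMIM:613983	24148	PRPF6
ORPHA:791	9129	PRPF3
OMIM:613827	2979	GUCA1B
ORPHA:791	57670	KIAA1549
OMIM:611131	10002	NR2E3
ORPHA:791	583	BBS2
OMIM:615434	23568	ARL2BP
ORPHA:791	145226	RDH12
OMIM:610359	23020	SNRNP200
ORPHA:791	3419	IDH3A
OMIM:617123	55624	POMGNT1
ORPHA:791	7275	TUB
OMIM:613769	5995	RGR
ORPHA:791	762	CA4
OMIM:551500	4508	ATP6
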