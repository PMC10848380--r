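entrez_id	symbol	direction
57468	SLC12A5	up
2554	GABRA1	up
2564	GABRE	up
2902	GRIN1	up
2742	GLRA2	up
6785	ELOVL4	down
240	ALOX5	up
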