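symbol	entrez_id	drug_name	drug_id	action
ALOX5	240	Sulfasalazine	DB00795	Inhibitor
ALOX5	240	Diethylcarbamazine	DB00711	Inhibitor
ALOX5	240	Mesalazine	DB00244	Inhibitor
ALOX5	240	Balsalazide	DB01014	Inhibitor
ALOX5	240	Masoprocol	DB00179	Inhibitor
ALOX5	240	Meclofenamic acid	DB00939	Inhibitor
ELOVL4	6785	Omega-3-carboxylic acids	DB09568	Potentiator
GABRA1	2554	Methohexital	DB00474	Antagonist
GABRA1	2554	Flumazenil	DB01205	Antagonist
GLRA2	2742	Taurine	DB01956	Agonist
GRIN1	2902	Orphenadrine	DB01173	Antagonist
SLC12A5	57468	Bumetanide	DB00887	Inhibitor
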