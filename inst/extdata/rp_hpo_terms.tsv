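term_id	term_name	specificity
HP:0000035	Abnormal testis morphology	9
HP:0000135	Hypogonadism	8
HP:0000405	Conductive hearing impairment	10
HP:0000407	Sensorineural hearing impairment	10
HP:0000431	Wide nasal bridge	8
HP:0000463	Anteverted nares	11
HP:0000518	Cataract	7
HP:0000563	Keratoconus	11
HP:0000602	Ophthalmoplegia	7
HP:0000613	Photophobia	9
HP:0000618	Blindness	8
HP:0000639	Nystagmus	7
HP:0000648	Optic atrophy	9
HP:0000842	Hyperinsulinemia	10
HP:0000987	Atypical scarring of skin	9
HP:0001249	Intellectual disability	7
HP:0001347	Hyperreflexia	7
HP:0005978	Type II diabetes mellitus	9
HP:0007675	Progressive night blindness	7
HP:0007703	Abnormality of retinal pigmentation	8
HP:0008046	Abnormal retinal vascular morphology	11
HP:0008736	Hypoplasia of penis	12
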