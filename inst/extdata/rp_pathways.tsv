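pathway_id	pathway_name	rp_genes
hsa04010	MAPK signaling pathway	KRAS
hsa04012	ErbB signaling pathway	KRAS
hsa04014	Ras signaling pathway	KRAS
hsa04015	Rap1 signaling pathway	KRAS
hsa04022	cGMP-PKG signaling pathway	CNGB1;CNGA1;GTF2I;GTF2IRD1
hsa04024	cAMP signaling pathway	CNGB1;CNGA1
hsa04062	Chemokine signaling pathway	KRAS
hsa04066	HIF-1 signaling pathway	HK1
hsa04068	FoxO signaling pathway	KRAS
hsa04071	Sphingolipid signaling pathway	KRAS
hsa04072	Phospholipase D signaling pathway	KRAS
hsa04150	mTOR signaling pathway	KRAS
hsa04151	PI3K-Akt signaling pathway	KRAS
hsa04210	Apoptosis	KRAS
hsa04211	Longevity regulating pathway—mammal	KRAS
hsa04340	Hedgehog signaling pathway	SUFU
hsa04360	Axon guidance	SEMA4A;KRAS;LIMK1
hsa04370	VEGF signaling pathway	KRAS
hsa04530	Tight junction	KRAS
hsa04540	Gap junction	GJA1;KRAS
hsa04550	Signaling pathways regulating pluripotency of stem cells	KRAS
hsa04650	Natural killer cell mediated cytotoxicity	KRAS
hsa04660	T cell receptor signaling pathway	KRAS
hsa04662	B cell receptor signaling pathway	KRAS
hsa04664	Fc epsilon RI signaling pathway	KRAS
hsa04666	Fc gamma R-mediated phagocytosis	LIMK1
hsa04722	Neurotrophin signaling pathway	KRAS
hsa04725	Cholinergic synapse	KRAS
hsa04726	Serotonergic synapse	KRAS
hsa04727	GABAergic synapse	GABRD
hsa04810	Regulation of actin cytoskeleton	KRAS;LIMK1
hsa04910	Insulin signaling pathway	HK1;KRAS
hsa04912	GnRH signaling pathway	KRAS
hsa04914	Progesterone-mediated oocyte maturation	KRAS
hsa04915	Estrogen signaling pathway	KRAS
hsa04916	Melanogenesis	KRAS
hsa04917	Prolactin signaling pathway	KRAS
hsa04919	Thyroid hormone signaling pathway	KRAS
hsa04921	Oxytocin signaling pathway	KRAS
hsa04960	Aldosterone-regulated sodium reabsorption	KRAS
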