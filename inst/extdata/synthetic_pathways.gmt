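hsa04261	Adrenergic signaling in cardiomyocytes	G08B	G02B	G22B	G09A
hsa04925	Aldosterone synthesis and secretion	G11A	G23A	G22B	G16A
hsa04020	Calcium signaling	G16B	G07B	G18A	G09A
hsa04260	Cardiac muscle contraction	G19B	G13A	G03B	G12B
hsa04010	MAPK signaling pathway	G05B	G24B	G07B	G08B
hsa04080	Neuroactive ligand receptor interaction	G13B	G02B	G16A	G18B
hsa04614	Renin-angiotensin system	G02A	G15B	G21B	G21A
hsa04924	Renin secretion	G14A	G19B	G07A	G06B
hsa04022	cGMP-PKG signaling pathway	G07A	G21B	G13B	G19B
hsa04024	cAMP signaling pathway	G15A	G17A	G01A	G14B
hsa04270	Vascular smooth muscle contraction	G21B	G09A	G13B	G11B
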