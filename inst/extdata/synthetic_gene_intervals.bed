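1	1	99985	G01A
1	99986	199970	G01B
1	600001	699985	G02A
1	699986	799970	G02B
1	1200001	1299985	G03A
1	1299986	1399970	G03B
1	1800001	1899985	G04A
1	1899986	1999970	G04B
1	2400001	2499985	G05A
1	2499986	2599970	G05B
1	3000001	3099985	G06A
1	3099986	3199970	G06B
1	3600001	3699985	G07A
1	3699986	3799970	G07B
1	4200001	4299985	G08A
1	4299986	4399970	G08B
1	4800001	4899985	G09A
1	4899986	4999970	G09B
1	5400001	5499985	G10A
1	5499986	5599970	G10B
1	6000001	6099985	G11A
1	6099986	6199970	G11B
1	6600001	6699985	G12A
1	6699986	6799970	G12B
1	7200001	7299985	G13A
1	7299986	7399970	G13B
1	7800001	7899985	G14A
1	7899986	7999970	G14B
1	8400001	8499985	G15A
1	8499986	8599970	G15B
1	9000001	9099985	G16A
1	9099986	9199970	G16B
1	9600001	9699985	G17A
1	9699986	9799970	G17B
1	10200001	10299985	G18A
1	10299986	10399970	G18B
1	10800001	10899985	G19A
1	10899986	10999970	G19B
1	11400001	11499985	G20A
1	11499986	11599970	G20B
1	12000001	12099985	G21A
1	12099986	12199970	G21B
1	12600001	12699985	G22A
1	12699986	12799970	G22B
1	13200001	13299985	G23A
1	13299986	13399970	G23B
1	13800001	13899985	G24A
1	13899986	13999970	G24B
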