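motif	bin
GGA/GAG/AGG	SD_Canonical
3Base_5BMM	SD_Canonical
4Base_6BMM	SD_Canonical
AGG	SD_Canonical
GGA	SD_Canonical
GAG	SD_Canonical
AGGA	SD_Canonical
GGAG	SD_Canonical
GAGG	SD_Canonical
AGGAG	SD_Canonical
GGAGG	SD_Canonical
AGGAGG	SD_Canonical
AGGA/GGAG/GAGG	SD_Canonical
AGGAG/GGAGG	SD_Canonical
AGGAG(G)/GGAGG	SD_Canonical
AGxAG	SD_Canonical
AGGxGG	SD_Canonical
AGxAGG/AGGxGG	SD_Canonical
GGxGG	SD_Canonical
TAA	SD_Bacteroidetes
TAAA	SD_Bacteroidetes
TAAAA	SD_Bacteroidetes
TAA/TAAA/TAAAA	SD_Bacteroidetes
TATATA	TATATA_3-6
TATATA_3-6	TATATA_3-6
AAAAA	OnlyA
AAAA	OnlyA
AAA	OnlyA
TTTTT	OnlyT
TTTT	OnlyT
TTT	OnlyT
AAxAA	DoubleA
AATAA	DoubleA
AACAA	DoubleA
TTxTT	DoubleT
TTATT	DoubleT
TTCTT	DoubleT
GA	Other_GA
GAxGA	Other_GA
GAGAGA	Other_GA
No_A	NoA
NoA	NoA
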