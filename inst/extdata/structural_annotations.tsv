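taxon	character_id	state	note
PDI	S.pair15-biarmed	1	pericentric inversion: pair 15 metacentric in PDI
PHA	S.pair15-biarmed	0	pair 15 acrocentric
LSI	S.pair15-biarmed	0	pair 15 acrocentric
TSA	S.pair15-biarmed	?	no pair-15 homolog distinguishable
LSI	S.CH-15q	1	whole long arm of pair 15 heterochromatic
PHA	S.CH-15q	0
PDI	S.CH-15q	0
TSA	S.CH-15q	?
LSI	S.CH-Y	1	whole long arm of Y heterochromatic
PHA	S.CH-Y	0
PDI	S.CH-Y	0
TSA	S.CH-Y	0
LSI	S.NOR-16p	1	second NOR on short arm of pair 16
PHA	S.NOR-16p	0
PDI	S.NOR-16p	0
TSA	S.NOR-16p	?
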