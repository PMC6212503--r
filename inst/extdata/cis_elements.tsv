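name	consensus	annotation
HSE	AGAAAATTCG	heat shock responsive element
ARE	TGGTTT	anaerobic induction element
LTR	CCGAAA	low temperature responsive element
ABRE	TACGTG	abscisic acid responsive element
CGTCA-motif	CGTCA	methyl jasmonate responsive element (pairs with TGACG-motif)
TGACG-motif	TGACG	methyl jasmonate responsive element (pairs with CGTCA-motif)
ERE	ATTTCAAA	ethylene responsive element
TCA-element	CCATCTTTTT	salicylic acid responsive element
W-box	TTGACC	pathogen/wounding responsive WRKY binding site
TC-rich	GTTTTCTTAC	defense and stress responsive element
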