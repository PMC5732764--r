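Folate Metabolism	editable starting set	FOLH1	SLC19A1	FPGS	DHFR	TYMS	MTHFR	SLC3A2
Folate One-Carbon Metabolism	editable starting set	TYMS	TK1	MTHFR	FPGS	SLC19A1	SHMT1	MTR	MTHFD1
Polyamine Metabolism	editable starting set	ODC1	AMD1	SRM	SMS	SAT1	MTAP	SLC3A2
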