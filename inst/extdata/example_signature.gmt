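TGFB_PCA_SIGNATURE	six-gene co-culture derived set	SERPINE1	TGFB1	JUNB	SMAD7	SKIL	PMEPA1
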