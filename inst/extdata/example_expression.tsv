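gene_id	sampleA	sampleB
TGFB1	8.25	7.5
SERPINE1	10	9.125
JUNB	6.5	6.75
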