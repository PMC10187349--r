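sample_id	gene	copies_lost
S1	PTEN	1
S1	TP53	1
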