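Tumor_Sample_Barcode	Hugo_Symbol	oncogenic
S1	TP53	Likely Oncogenic
S1	KRAS	Oncogenic
S1	TP53	VUS
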