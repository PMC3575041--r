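#MIM_number	GeneID
611731	APC
611731	TP53
175100	APC
120436	MLH1
190070	KRAS
164790	BRAF
120435	MSH2
114480	BRCA1
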