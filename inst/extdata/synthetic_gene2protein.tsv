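#GeneID	protein_accession
APC	NP_000029.2
TP53	NP_000537.3
TP53	NP_001119584.1
MLH1	NP_000240.1
KRAS	NP_004976.2
BRAF	NP_004324.2
MSH2	NP_000242.1
BRCA1	NP_009225.1
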