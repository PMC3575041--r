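#GeneID	PubMed_ID
APC	1528264
APC	8162022
TP53	2047879
TP53	1905840
MLH1	8145827
KRAS	3122217
BRAF	12068308
MSH2	8252616
BRCA1	7545954
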