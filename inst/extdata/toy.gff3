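##gff-version 3
chrT	stochm6a	CDS	101	300	.	+	0	ID=toyA
chrT	stochm6a	CDS	401	600	.	-	0	ID=toyB
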