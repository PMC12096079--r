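transcript_id	pos	ref	a_count	g_count	other_count
toyA	2	A	1	99	0
toyA	29	A	0	100	0
toyA	65	A	2	98	0
toyA	74	A	95	5	0
toyA	91	A	50	50	0
toyA	134	A	1	9	0
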