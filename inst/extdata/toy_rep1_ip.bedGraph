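chrT	100	150	10
chrT	150	200	90
chrT	200	300	10
chrT	400	600	10
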