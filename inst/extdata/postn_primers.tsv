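name	sequence	role
F1	CTTCAAAGAAATCCCCGTGAC	forward
F2	GGAGGTGGAGAAACAGAAGAAA	forward
R1	TCTTCTGTTTCTCCACCTCCA	reverse
R2	CAACTTCCTCACGGGTGTGT	reverse
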