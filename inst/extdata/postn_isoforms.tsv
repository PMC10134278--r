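name	exons_missing	accession
Iso1	None	NP_006466.2
Iso2	17, 18	NP_001129406.1
Iso3	17, 21	NP_001129407.1
Iso4	17, 18, 21	NP_001129408.1
Iso5	17	NP_001273594.1
Iso6	17, 18, 19	NP_001273595.1
Iso7	17, 18, 19, 21	NP_001273596.1
Iso8	21	NP_001317446.1
Iso9	18, 21
Iso10	18
Iso11	18, 19
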