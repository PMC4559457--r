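name	role	sequence
Pds5b_F	forward	GGACTATTTACAGGAAACGTC
Pds5b_R	reverse	AGCAAGCCACCAGTAAACG
Her2_F	forward	GTCACAGGGGCCTCATCC
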