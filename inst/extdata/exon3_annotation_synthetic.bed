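chr5	150719822	150719972	Pds5b_exon3	0	+
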