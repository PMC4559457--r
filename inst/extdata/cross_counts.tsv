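stage	wt	het	hom
E16_to_birth	14	25	0
E15	7	22	11
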