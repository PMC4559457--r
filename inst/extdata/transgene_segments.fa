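>vector_remnant_34nt
CTGGGGATCCTCTAGAGTCGACCTGCAGGCATGC
>utr5_variant_36nt
AGGGGAGGTAACCCTGGCCCCTTTGGTCGGGGCCCC
>missing_polyA_61nt
ATGAAATAAAGACCCAGGGGGAGAAGCTGGGATCCTCTAGAGTCGACGCATGCAAGCTTNA
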