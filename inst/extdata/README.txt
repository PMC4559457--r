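cross_counts.tsv      genotype counts per developmental stage from a
                      heterozygote intercross (wt : het : hom per stage)
genotyping_primers.tsv  published genotyping primer sequences; Her2_F is the
                      junction-spanning primer (14 nt transgene + 4 nt host)
exon3_annotation_synthetic.bed  single-exon annotation of the disrupted gene;
                      the exon START coordinate is the published one, the
                      exon end is a synthetic stand-in (the true exon extent
                      is not reproduced here)
transgene_segments.fa the three published transgene-model difference
                      segments (34 nt vector remnant, 36 nt 5'UTR variant
                      segment, 61 nt missing poly-A segment; contains one
                      ambiguous N as published)
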