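#!/usr/bin/env Rscript
# Split-read breakpoint calling: cluster soft-clipped alignments, realign
# the clipped consensus sequences against the full reference, and emit
# fusion calls. On the simulated study exactly three fusions overlap the
# transgene: the tandem concatemer junction (whose support scales with copy
# number), the host-to-transgene entry and the transgene-to-host exit.

library(concatmap)

reference <- read_fasta("results/fixture/reference.fa")
aln <- read_sam("results/alignments.sam")

fusions <- call_fusions(aln, reference, min_clip_len = 20, min_support = 3)
write_fusions(fusions, "results/fusions.tsv")
write_fusions_bedpe(fusions, "results/fusions.bedpe")

cat("fusions called:", nrow(fusions), "\n")
print(fusions[, c("ref_a", "pos_a", "ref_b", "pos_b", "support")])
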