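#!/usr/bin/env Rscript
# Build the simulated study: a diploid mouse-like genome in which one
# haplotype carries a 12-copy head-to-tail transgene concatemer inserted at
# a single site with a 10 nt target-site duplication (difference
# convention), and 100 nt paired-end reads at 12x per haplotype with 0.002
# substitution errors. Everything downstream works from these files plus
# the recorded ground truth.

library(concatmap)

seed <- 1L
outdir <- "results/fixture"

cfg <- default_config()
fix <- make_fixture(cfg, seed)
paths <- write_fixture(fix, outdir)

cat("haplotype lengths:", nchar(fix$haplotypes), "\n")
cat("read pairs simulated:", nrow(fix$reads), "\n")
cat("ground truth: entry", fix$truth$entry_host, "exit", fix$truth$exit_host,
    "tsd", fix$truth$tsd_len, "copies", fix$truth$copies, "\n")
cat("written:", paste(paths, collapse = "\n         "), "\n")
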