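#!/usr/bin/env Rscript
# Transgene-model work in two parts.
#
# 1. Iterative refinement demonstration: start from a model carrying three
#    planted substitutions, map reads simulated from the true construct at
#    15x with sequencing errors, and let the map -> pileup-consensus loop
#    correct the model.
#
# 2. Model diffing: compare sequences differing by the three published
#    segments (a 34 nt cloning-vector remnant at the 5' end, a 36 nt 5'UTR
#    variant segment, and a 61 nt segment containing the poly-A signal that
#    is absent from the sequenced construct) and recover each as one
#    variant call.

library(concatmap)

dir.create("results/model", showWarnings = FALSE, recursive = TRUE)
set.seed(3L)

truth <- make_transgene_model(6884, "transgene")
bad <- truth$sequence
planted <- c(1200L, 3500L, 6000L)
for (p in planted)
  substr(bad, p, p) <- chartr("ACGT", "CGTA", substr(bad, p, p))
start_model <- transgene_model("transgene", bad)

reads <- simulate_reads(c(construct = truth$sequence), depth = 15,
                        err_rate = 0.002)
ref <- iterate_refinement(reads, character(0), start_model)
cat("refinement:", ref$iterations, "iteration(s), converged:",
    ref$converged, "\n")
cat("planted substitutions corrected:",
    ref$model$sequence == truth$sequence, "\n")

segs <- read_fasta(system.file("extdata", "transgene_segments.fa",
                               package = "concatmap"))
# published construct: no vector remnant, no variant segment, poly-A present
published <- paste0(substr(truth$sequence, 35, 3000),
                    substr(truth$sequence, 3037, 6823),
                    segs[["missing_polyA_61nt"]])
# sequenced model: remnant + variant segment gained, poly-A segment lost
sequenced <- paste0(segs[["vector_remnant_34nt"]],
                    substr(truth$sequence, 35, 3000),
                    segs[["utr5_variant_36nt"]],
                    substr(truth$sequence, 3037, 6823))
variants <- diff_models(sequenced, published)
write_variants(variants, "results/model/model_variants.tsv")
cat("variant calls between the two model versions:\n")
print(variants[, c("kind", "position", "length")])
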