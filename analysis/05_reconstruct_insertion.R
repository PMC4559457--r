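#!/usr/bin/env Rscript
# Turn the fusion calls and the depth profile into a reconstructed
# insertion allele: entry/exit breakpoints, target-site duplication,
# orientation, concatemer copy number (depth and junction estimators), the
# total inserted length, and the insertion's position relative to the
# nearest annotated exon.

library(concatmap)

reference <- read_fasta("results/fixture/reference.fa")
truth <- jsonlite::read_json("results/fixture/truth.json")
aln <- read_sam("results/alignments.sam")
fusions <- read.table("results/fusions.tsv", header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)

cls <- classify_fusions(fusions, "transgene")
allele <- reconstruct_insertion(cls$entry_fusions[1, ],
                                cls$exit_fusions[1, ],
                                cls$self_fusions[1, ],
                                reference[["host1"]])

lens <- setNames(nchar(reference), names(reference))
profile <- depth_profile(aln, lens, window = 500)
est <- estimate_copy_number(profile, "transgene", truth$zygosity,
                            geometry = allele,
                            insertion_site = list(contig = "host1",
                                                  pos = allele$entry_host))
allele$copies_depth <- est$copies_depth
allele$copies_junction <- junction_copy_estimate(
  cls$self_fusions$support[1], cls$entry_fusions$support[1],
  cls$exit_fusions$support[1], correction = TRUE)
allele$total_insert_len <- total_insert_length(
  allele, round(est$copies_depth))$exact_nt

# a synthetic exon annotation 19 nt downstream of the entry breakpoint,
# mirroring the disrupted-gene geometry at desk scale
ann <- data.frame(chrom = "host1", start = allele$entry_host + 19L,
                  end = allele$entry_host + 169L, name = "exon3_like",
                  strand = "+", stringsAsFactors = FALSE)
near <- annotate_position(allele, ann)

report <- c(unclass(allele),
            list(copies_naive = est$copies_naive,
                 nearest_feature = near,
                 truth = truth))
write_json <- function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                  digits = NA, pretty = TRUE)
write_json(report, "results/insertion_report.json")

print(allele)
cat("truth entry/exit/tsd:", truth$entry_host, truth$exit_host,
    truth$tsd_len, "\n")
cat(sprintf("copy number: depth %.2f (naive ratio %.2f), junction %.2f\n",
            est$copies_depth, est$copies_naive, allele$copies_junction))
cat(sprintf("insertion is %d nt %s of %s\n", near$distance, near$relation,
            near$feature))
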