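---
title: "Mapping transgene concatemer integrations from short-read WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transgene concatemer integrations from short-read WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Classical transgenesis by pronuclear microinjection integrates the injected
construct at a random genomic site, usually after the linearized molecules
re-circularize and recombine into a long head-to-tail concatemer. A single
integration event therefore has a characteristic architecture: host sequence,
a truncated first copy of the transgene, N−2 full head-to-tail unit copies, a
truncated last copy, and host sequence again, with a short stretch of host
sequence duplicated on both flanks (the target-site duplication, TSD) left by
the staggered integration. When the site falls inside an essential gene, the
insertion phenotype (for example homozygous embryonic lethality with normal
heterozygotes) has nothing to do with the transgene product itself.

`concatmap` implements the complete inference chain by which whole-genome
sequencing resolves such an event, end to end and testably at desk scale:

1. **simulate** a diploid genome with a known concatemer insertion and
   paired-end reads from it;
2. **map** the reads locally (with soft clipping) against a concatenated
   reference containing the host contigs and *one* copy of the transgene
   model;
3. **refine** the transgene model from pileups (map → consensus → remap);
4. **call** split-read fusions by clustering soft clips and realigning their
   consensus sequences;
5. **infer** the insertion allele: entry/exit breakpoints, TSD, orientation,
   copy number (depth and junction estimators), total insert length, and the
   position relative to annotated exons;
6. **genotype** individuals by in-silico junction PCR and test Mendelian
   segregation across an intercross.

# Coordinate and TSD conventions

All coordinates are 1-based inclusive; BED input/output converts at the
boundary (0-based half-open to 1-based inclusive).

The simulated insertion allele is

```
host[1 .. entry_host] + concatemer + host[exit_host .. end]
```

so the inclusive host span `[exit_host, entry_host]` appears verbatim on both
flanks of the insertion — that span is the physical target-site duplication.
`tsd_len` is nevertheless reported as the breakpoint *difference*
`entry_host − exit_host`, the convention in which a 10 nt duplication is
printed for breakpoints ten positions apart even though the inclusive span
contains eleven bases; `tsd_seq` carries the full inclusive span
(`tsd_len + 1` bases). We adopt the difference convention because it is the
one under which the breakpoint caller's natural coordinates — the last base
of the 5′ side and the first base of the 3′ side of each junction — are
mutually consistent across the entry fusion, the exit fusion, and the TSD
arithmetic. One consequence is that a "blunt" insertion (`tsd_len = 0`)
still duplicates a single base; an insertion with a true deletion at the
site would have a negative difference and is representable (flagged) but not
generated by the simulator.

The concatemer is described by four transgene coordinates: `entry_tg`, the
first base of the first (5′-truncated) copy; `unit_end_tg`, the base at
which every internal copy ends before looping back to position 1;
`exit_tg`, the last base of the final (3′-truncated) copy; and the copy
count. Whether the unit end reflects a per-copy truncation or only the
terminal copies is in general not knowable from junctions alone, so
`unit_end_tg` is an explicit parameter of the generator rather than a
guess; the default study uses a 6884 nt model whose units end at 6850.

# What the simulator emulates, and what it does not

`make_fixture()` draws a uniform-composition host contig (default 200 kb at
42% GC) and a random transgene model with a promoter/5′UTR/ORF/3′UTR feature
layout, builds the insertion haplotype, and simulates paired-end reads:
uniformly placed fragments with truncated-normal lengths (600 ± 60 nt,
clipped to `[read_len, 2 × frag_mean]`), 100 nt reads from a random strand
per fragment (read 2 the reverse complement of the fragment's 3′ end),
i.i.d. substitution errors (default 0.002/base), and constant base
qualities. The default depth is 12× per haplotype, heterozygous for the
insertion.

It deliberately does **not** emulate GC-coverage bias, indel or
quality-profiled errors, PCR/optical duplicates, repetitive host sequence,
or any structural variation beyond the one insertion. Passing tests
therefore demonstrate the correctness of the inference logic under the
stated read model, not robustness to every artefact of real libraries; on
real data the external-mapper equivalents of steps 2–4 face additional
noise sources (multi-mapping repeats foremost) that the random host does
not produce.

One generator choice deserves emphasis. A split-read junction coordinate is
only defined up to (near-)homology between the joined sequences: a local
aligner will extend an anchor across the junction whenever the reference
continuation scores net-positive against the read, which shifts the observed
clip boundary and makes "the" breakpoint ambiguous by a few bases even on
error-free data. So that ground-truth coordinates are well defined, the
generator resamples the reference bases adjacent to each junction until no
prefix of any cross-junction extension scores ≥ 0 under the mapper's scoring
(+2/−3, checked over a 16 nt window, iterated to a joint fixed point across
the five junction/direction combinations). Real junctions enjoy no such
guarantee; the caller therefore also implements the real-data behaviour —
microhomology is reported once and the junction placed at its leftmost
consistent position — and that path is exercised on a constructed
microhomology fixture in the tests.

# Mapping

The mapper is an exact-k-mer seed-and-extend local aligner (k = 20 by
default; ≥ 1 exact seed required) with ungapped extension: the best
local segment along each seed diagonal is found by maximum-subarray scan
with match +2, mismatch −3, and free soft clips. Gapped extension is
intentionally absent — with no indel errors simulated, junction detection
rests entirely on clipping, and an ungapped scan is exactly solvable and
fast. Ties are broken deterministically (lexicographically lowest contig,
lowest start, + strand). k = 20 leaves multiple exact seeds per 100 nt read
at the default error rate. On references up to a few kb the mapper is
checked read-for-read against independent exhaustive local dynamic
programming (`Biostrings::pairwiseAlignment` with prohibitive gap
penalties).

Because the reference carries a single copy of the transgene, every read
from any concatemer unit maps to that one contig: multi-mapping inside the
concatemer collapses by construction, and transgene depth becomes the
copy-number signal. This concatenated-reference design is the central trick
the whole analysis relies on.

# Breakpoint calling

Soft clips of at least `min_clip_len` (20 nt) are grouped by (contig, clip
boundary ± 3 nt, side); each cluster's per-column majority consensus
(ties → N) is realigned against the full reference, joining the cluster
boundary to the realigned locus as a fusion oriented 5′→3′ along the fused
sequence. Unaligned clip prefixes that match neither side are reported as
untemplated sequence.

Three accounting decisions matter at ~10× depth and are worth stating:

* Clusters are collected without a support floor, and `min_support` (3) is
  applied to the merged per-junction total. The split reads of one junction
  divide between its two flanks (host-anchored and transgene-anchored);
  thresholding each flank separately at 3 loses real junctions when only
  5–7 reads span them.
* Fusion calls on the same junction *diagonal* (equal `pos_a − pos_b`)
  within 25 nt are merged, with coordinates decided by a support-weighted
  vote over identical boundary pairs. Near-homology with an internal
  mismatch can carry anchors a few bases across a junction and produce a
  coherently shifted duplicate call; the vote keeps the boundary most reads
  clip at.
* After merging, support is recounted as the number of clips ≥ 8 nt
  abutting either boundary (± 10 nt). Discovery needs clips long enough to
  realign uniquely (20 nt); support only needs an unambiguous boundary
  match, and the longer threshold would systematically undercount.

# Copy number

Two estimators are reported and cross-checked (disagreement > 20% is
flagged):

**Depth.** The per-haplotype depth *h* is half the median host window depth
(500 nt windows; 2 kb around the insertion site excluded). The naive ratio
`median transgene depth / h` measures mean copy *multiplicity*, which on a
concatemer with truncated terminal copies is ≈ N−1, not N: when
`entry_tg > exit_tg` no transgene base lies in all N copies. At publication
scale (a hundred-plus copies) the deficit disappears into rounding, but at
a 12-copy desk scale it is a whole copy. The estimator therefore inverts
the exact expected aligned-base total,
`T = h × [(unit_end − entry + 1) + (N − 2)·unit_end + exit]`,
for N, using the junction geometry recovered from the fusions; the naive
ratio is reported alongside. On the default study the corrected estimate
rounds to the true count on every replicate seed.

**Junction support.** A concatemer of N copies has N−1 tandem junctions per
haplotype against one entry and one exit junction, so
`copies = self_support / mean(entry, exit) + 1`. The denominators are
single-site Poisson counts (λ ≈ 10 at 12×), giving the plain ratio a
sampling sd of about 3 copies and the upward bias of `E[1/x]`; the pipeline
applies the standard add-one pooled-denominator correction,
`2·self/(entry + exit + 1) + 1`. This estimator is intrinsically noisy at
these depths and serves as an independent consistency check on the depth
estimator, not as the primary call.

# Model refinement and diffing

`refine_model()` applies a conservative pileup consensus to the transgene
contig: positions with depth ≥ 5 where a non-reference base reaches 80%
are replaced, and the caller loops map → refine to convergence (a planted
3-substitution model at 15× with sequencing errors converges in two
iterations with zero false edits). Only substitutions are refined;
length-changing differences are the province of `diff_models()`, which
globally aligns two model versions (match +1, mismatch −2, gap −4 to open
and −1 per additional base, via `Biostrings::pairwiseAlignment`) and emits
a merged variant list on reference coordinates that round-trips exactly
through `apply_variants()`. The published 34/36/61 nt difference segments
are bundled as plain-text inputs and each recovered as a single variant
call of the printed length.

# Genotyping and segregation

`find_primer_sites()` implements annealing with a 3′-exact-match rule (one
mismatch tolerated elsewhere): a junction-spanning primer whose final 4 nt
anneal to host sequence cannot prime on an intact transgene copy or on the
wild-type locus, which is what makes single-tube three-primer genotyping
work. `design_genotyping_primers()` reproduces this design on a simulated
study, placing the host primer pair so the junction and wild-type products
have the published 194/202 bp lengths; `call_genotype()` maps band patterns
to tg/tg, tg/wt, wt/wt with a ±3 bp tolerance and returns `indeterminate`
for anything else. `cross_statistics()` reports per-stage genotype
percentages, the pooled carrier percentage against the Mendelian
expectation (75% carriers from a het × het cross), and a chi-square
goodness-of-fit per stage — the chi-square is convenience output, not part
of the original assay. `simulate_cross()` draws 1:2:1 genotypes with
per-genotype viabilities; homozygote viability 0 reproduces the qualitative
pattern of homozygotes present at early stages and absent later, with
carriers approaching 2/3 of survivors.

# Problem sizes and numerical choices

The default study is a 200 kb host contig with a 12-copy concatemer
(~274 kb insertion haplotype) at 12× per haplotype — about 28,500 read
pairs — which one pipeline run processes in under ten seconds; the
replicate study in the acceptance tests runs 20 such seeds. Unit tests use
a 40 kb / 3-copy toy geometry. These sizes were chosen so the full junction
architecture (both host junctions plus the tandem junction, truncated
terminal copies, TSD) is present with enough depth for every estimator to
be meaningfully tested, while the whole suite stays fast enough to run
habitually.

Other numerical choices: alignment tie-breaks as above; clip-consensus ties
become N (never counted as support for a base); depth medians rather than
means throughout for robustness to junction-overlapping windows; the
content hash stamped into reports is a simple 31-ary polynomial hash of the
canonical JSON config (stability, not cryptography). Degenerate inputs are
contracts, not surprises: zero-coverage refinement warns and converges
unchanged, an empty fusion set classifies into four empty sets, zero host
depth is an error for copy-number estimation, and zero host-junction
support makes the junction estimator unavailable rather than infinite.

# Known limitations

* Single-site, single-orientation events only; multi-site integrations are
  detected (entry/exit on different contigs) but not reconstructed.
* The depth estimator's geometry correction requires the junction geometry;
  without fusions it falls back to the naive ratio and inherits its ≈ N−1
  bias on truncated-terminal concatemers.
* Reverse-orientation concatemers are representable in the generator and
  the fusion caller records inverted junctions, but microhomology
  annotation and support recounting are implemented for forward-forward
  junctions only.
* The genotyping model is product-logic only: no melting temperatures,
  primer dimers, or amplification efficiency.
* On real libraries, repeat-induced multi-mapping, GC bias and duplicate
  reads would all perturb the depth estimator; the simulator intentionally
  omits them, so real-data use would put an external GC-corrected CNV tool
  in its place.
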