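#' Index a reference for seed-and-extend mapping
#'
#' Builds an exact k-mer index over a set of named contigs (typically the
#' host contigs concatenated with the single-copy transgene model, the
#' design under which depth over the transgene contig encodes concatemer
#' copy number). Both strands are handled at query time by
#' reverse-complementing the read.
#'
#' @param contigs named character vector of reference sequences.
#' @param k seed length in nt (>= 8).
#' @return object of class `ref_index`.
#' @export
index_reference <- function(contigs, k = 20L) {
  if (length(contigs) == 0) stop("contigs must be non-empty")
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop("contigs must be named")
  if (k < 1L || k > 31L) stop("seed length k must be in [1, 31]")
  short <- nchar(contigs) < k
  if (any(short))
    warning("skipping contig(s) shorter than k: ",
            paste(names(contigs)[short], collapse = ", "))
  ptr <- cpp_index_reference(names(contigs), unname(contigs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), names = names(contigs),
                 lengths = setNames(nchar(contigs), names(contigs))),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat("k-mer reference index: k =", x$k, ",", length(x$names),
      "contig(s),", sum(x$lengths), "nt\n")
  invisible(x)
}

#' Look up the reference occurrences of one k-mer
#'
#' @param index a [index_reference()] object.
#' @param kmer a string of exactly `index$k` nt.
#' @return data.frame with columns ref_name and pos (1-based).
#' @export
lookup_kmer <- function(index, kmer) {
  cpp_lookup_kmer(index$ptr, kmer)
}

# batch alignment returning the internal alignment data.frame (seq/qual in
# aligned orientation).
align_batch <- function(reads, index, match = 2L, mismatch = -3L,
                        quals = NULL, ids = NULL, mate = NA_integer_,
                        max_hits_per_kmer = 100L) {
  res <- cpp_align_batch(index$ptr, reads, as.integer(match),
                         as.integer(mismatch), as.integer(max_hits_per_kmer))
  rev <- res$reverse & !is.na(res$ref_id)
  seq <- reads
  if (any(rev)) seq[rev] <- revcomp(reads[rev])
  if (is.null(quals)) quals <- strrep("I", nchar(reads))
  qual <- quals
  if (any(rev))
    qual[rev] <- vapply(strsplit(quals[rev], ""), function(q)
      paste(rev(q), collapse = ""), "")
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  data.frame(
    qname = ids,
    mate = rep(mate, length(reads)),
    rname = ifelse(is.na(res$ref_id), NA_character_,
                   index$names[res$ref_id]),
    pos = res$pos,
    strand = ifelse(is.na(res$ref_id), NA_character_,
                    ifelse(res$reverse, "-", "+")),
    clip_left = res$clip_left, m_len = res$m_len,
    clip_right = res$clip_right,
    score = res$score, nm = res$nm,
    seq = seq, qual = qual,
    stringsAsFactors = FALSE)
}

#' Align a single read
#'
#' Returns the highest-scoring ungapped local alignment over both strands;
#' bases outside the local alignment are soft-clipped. Ties are broken by
#' lexicographically lowest contig name, then lowest start, then + strand.
#'
#' @param read nucleotide string (length >= `index$k` to be mappable).
#' @param index a [index_reference()] object.
#' @param match,mismatch scoring (soft clips are free; no gaps).
#' @return one-row alignment data.frame; `pos` is `NA` when unmapped.
#' @export
align_read <- function(read, index, match = 2L, mismatch = -3L) {
  align_batch(read, index, match, mismatch, ids = "read")
}

#' Map read pairs to an indexed reference
#'
#' Each mate is aligned independently (pairing is recorded, not used to
#' constrain placement). The summary reports the mapped-read count, the
#' mapping rate and the mean depth implied by the aligned bases.
#'
#' @param pairs data.frame with columns id, seq1, seq2, qual1, qual2
#'   (as produced by [simulate_reads()] or [read_fastq_pairs()]).
#' @param index a [index_reference()] object.
#' @param match,mismatch scoring parameters.
#' @return list with `alignments` (data.frame, two rows per pair) and
#'   `summary` (n_reads, n_mapped, mapping_rate, haploid_coverage).
#' @export
map_pairs <- function(pairs, index, match = 2L, mismatch = -3L) {
  if (nrow(pairs) == 0) {
    aln <- align_batch(character(0), index)
    return(list(alignments = aln,
                summary = list(n_reads = 0L, n_mapped = 0L,
                               mapping_rate = NA_real_,
                               haploid_coverage = 0)))
  }
  a1 <- align_batch(pairs$seq1, index, match, mismatch,
                    quals = pairs$qual1, ids = pairs$id, mate = 1L)
  a2 <- align_batch(pairs$seq2, index, match, mismatch,
                    quals = pairs$qual2, ids = pairs$id, mate = 2L)
  aln <- rbind(a1, a2)
  aln <- aln[order(rep(seq_len(nrow(pairs)), 2L)), ]
  rownames(aln) <- NULL
  n <- nrow(aln)
  n_mapped <- sum(!is.na(aln$pos))
  list(alignments = aln,
       summary = list(
         n_reads = n,
         n_mapped = n_mapped,
         mapping_rate = n_mapped / n,
         haploid_coverage = sum(aln$m_len) / sum(index$lengths)))
}

#' Read paired FASTQ mate files
#'
#' @param r1,r2 FASTQ paths for mates 1 and 2.
#' @return pairs data.frame suitable for [map_pairs()].
#' @export
read_fastq_pairs <- function(r1, r2) {
  f1 <- read_fastq(r1)
  f2 <- read_fastq(r2)
  if (nrow(f1) != nrow(f2))
    stop("mismatched FASTQ mate files: ", nrow(f1), " vs ", nrow(f2),
         " records")
  id1 <- sub("/[12]$", "", f1$id)
  id2 <- sub("/[12]$", "", f2$id)
  if (!all(id1 == id2))
    stop("mismatched FASTQ mate files: read ids differ")
  data.frame(id = id1, seq1 = f1$seq, seq2 = f2$seq,
             qual1 = f1$qual, qual2 = f2$qual, stringsAsFactors = FALSE)
}
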