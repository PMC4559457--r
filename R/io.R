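#' @useDynLib concatmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rnorm runif setNames chisq.test
#' @importFrom utils read.table write.table
NULL

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings keeping sequences as named character
#' vectors, the representation used throughout the package.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read and write FASTQ
#'
#' @param ids,seqs,quals parallel character vectors.
#' @param path file path.
#' @return `read_fastq()` returns a data.frame with columns id, seq, qual.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  out <- character(4L * length(ids))
  idx <- seq_along(ids)
  out[4L * idx - 3L] <- paste0("@", ids)
  out[4L * idx - 2L] <- seqs
  out[4L * idx - 1L] <- "+"
  out[4L * idx] <- quals
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L)
    stop("truncated FASTQ: ", path, " has ", length(ln),
         " lines (not a multiple of 4)")
  idx <- seq_len(length(ln) / 4L)
  data.frame(id = sub("^@", "", ln[4L * idx - 3L]),
             seq = ln[4L * idx - 2L],
             qual = ln[4L * idx],
             stringsAsFactors = FALSE)
}

#' Parse a CIGAR string into (length, op) pairs
#'
#' Only the ops emitted by the local mapper (M, S) plus H/I/D are recognised.
#'
#' @param cigar a single CIGAR string.
#' @return data.frame with columns `len` and `op`.
#' @export
parse_cigar <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MSHID=X]", cigar))[[1]]
  if (length(lens) != length(ops))
    stop("malformed CIGAR: ", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

cigar_string <- function(clip_left, m_len, clip_right) {
  paste0(ifelse(clip_left > 0L, paste0(clip_left, "S"), ""),
         m_len, "M",
         ifelse(clip_right > 0L, paste0(clip_right, "S"), ""))
}

#' Write alignments as SAM
#'
#' Emits a minimal valid SAM file: `@HD`/`@SQ` header lines and one record per
#' mate, with soft clips in the CIGAR and unmapped reads retained (flag 0x4).
#'
#' @param aln alignment data.frame as produced by [map_pairs()].
#' @param ref_lengths named integer vector of reference contig lengths.
#' @param path output path.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref_lengths), "\tLN:", ref_lengths))
  mapped <- !is.na(aln$pos)
  flag <- rep(1L, nrow(aln))                       # paired
  flag <- flag + ifelse(mapped, 0L, 4L)            # unmapped
  flag <- flag + ifelse(mapped & aln$strand == "-", 16L, 0L)
  flag <- flag + ifelse(aln$mate == 1L, 64L, 128L) # first/second in pair
  cig <- ifelse(mapped, cigar_string(aln$clip_left, aln$m_len, aln$clip_right),
                "*")
  rec <- paste(aln$qname, flag,
               ifelse(mapped, aln$rname, "*"),
               ifelse(mapped, aln$pos, 0L),
               ifelse(mapped, 60L, 0L),
               cig, "*", 0L, 0L, aln$seq, aln$qual, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_sam
#' @return `read_sam()` returns an alignment data.frame (one row per record).
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "@")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 11L)
  if (length(bad))
    stop("malformed SAM record at line ",
         bad[1] + sum(startsWith(ln, "@")), " of ", path)
  f <- function(i) vapply(fields, `[[`, "", i)
  flag <- as.integer(f(2))
  cig <- f(6)
  clipl <- integer(length(cig)); mlen <- integer(length(cig))
  clipr <- integer(length(cig))
  for (i in seq_along(cig)) {
    if (cig[i] == "*") { clipl[i] <- NA; mlen[i] <- 0L; clipr[i] <- NA; next }
    p <- parse_cigar(cig[i])
    clipl[i] <- if (p$op[1] == "S") p$len[1] else 0L
    clipr[i] <- if (p$op[nrow(p)] == "S" && nrow(p) > 1) p$len[nrow(p)] else 0L
    mlen[i] <- sum(p$len[p$op %in% c("M", "=", "X")])
  }
  mapped <- bitwAnd(flag, 4L) == 0L
  data.frame(
    qname = f(1),
    rname = ifelse(mapped, f(3), NA_character_),
    pos = ifelse(mapped, as.integer(f(4)), NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    clip_left = clipl, m_len = mlen, clip_right = clipr,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    seq = f(10), qual = f(11),
    score = NA_integer_, nm = NA_integer_,
    stringsAsFactors = FALSE)
}

#' Read exon annotation from BED
#'
#' BED is 0-based half-open; coordinates are converted to the 1-based
#' inclusive convention used internally. Column 6 (strand) defaults to "+".
#'
#' @param path BED file path (3-6 columns).
#' @return data.frame with chrom, start, end (1-based inclusive), name, strand.
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED needs at least 3 columns: ", path)
  data.frame(
    chrom = tab[[1]],
    start = as.integer(tab[[2]]) + 1L,
    end = as.integer(tab[[3]]),
    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_,
    strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "+",
    stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param annot annotation data.frame in internal 1-based coordinates.
#' @export
write_bed <- function(annot, path) {
  tab <- data.frame(annot$chrom, annot$start - 1L, annot$end,
                    if (!is.null(annot$name)) annot$name else ".",
                    0L,
                    if (!is.null(annot$strand)) annot$strand else "+")
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# stable polynomial content hash for stamping reports (hex string)
content_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
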