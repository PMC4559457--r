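#' Construct a transgene model
#'
#' A transgene model is the reference sequence of the injected construct plus
#' named feature intervals (promoter, UTRs, ORF) in 1-based inclusive
#' coordinates.
#'
#' @param name identifier.
#' @param sequence nucleotide string over `{A,C,G,T,N}`.
#' @param features data.frame with columns `label`, `start`, `end`
#'   (1-based inclusive), all within the sequence.
#' @return object of class `transgene_model` (a list).
#' @export
transgene_model <- function(name, sequence, features = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  if (grepl("[^ACGTN]", sequence))
    stop("transgene sequence must be over {A,C,G,T,N}")
  L <- nchar(sequence)
  if (is.null(features))
    features <- data.frame(label = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
  stopifnot(all(c("label", "start", "end") %in% names(features)))
  if (nrow(features) &&
      (any(features$start < 1L) || any(features$end > L) ||
       any(features$start > features$end)))
    stop("feature intervals must lie within [1, ", L, "]")
  structure(list(name = name, sequence = sequence, features = features,
                 length = L),
            class = "transgene_model")
}

#' @export
print.transgene_model <- function(x, ...) {
  cat("transgene model '", x$name, "': ", x$length, " nt, ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' Generate a random transgene model
#'
#' Emulates a promoter-driven cDNA construct: a random sequence with a
#' promoter / 5' UTR / ORF / 3' UTR feature layout scaled to the requested
#' length (defaults mirror a 2.5 kb promoter driving a ~4.4 kb cDNA on a
#' 6884 nt construct).
#'
#' @param length construct length in nt.
#' @param name identifier.
#' @param gc_fraction expected GC content.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a [transgene_model()].
#' @export
make_transgene_model <- function(length = 6884L, name = "transgene",
                                 gc_fraction = 0.5, seed = NULL) {
  seq <- make_host_genome(length, gc_fraction, seed)
  b <- round(length * c(promoter = 0.363, utr5 = 0.026, orf = 0.547))
  cuts <- cumsum(b)
  features <- data.frame(
    label = c("promoter", "utr5", "orf", "utr3"),
    start = c(1L, cuts[1] + 1L, cuts[2] + 1L, cuts[3] + 1L),
    end = c(cuts[1], cuts[2], cuts[3], length),
    stringsAsFactors = FALSE)
  transgene_model(name, seq, features)
}

#' Generate a random host contig
#'
#' @param length contig length in nt (> 0).
#' @param gc_fraction expected GC proportion in `[0, 1]`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a nucleotide string of exactly `length` nt over `{A,C,G,T}`.
#' @export
make_host_genome <- function(length, gc_fraction = 0.42, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1L || length < 1)
    stop("length must be a positive integer")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
        collapse = "")
}

#' Describe a ground-truth insertion event
#'
#' Coordinates are 1-based inclusive. The insertion replaces nothing: the
#' host prefix ends at `entry_host` and the host suffix restarts at
#' `exit_host`, so the inclusive span `[exit_host, entry_host]` is physically
#' duplicated on both flanks (the target-site duplication). `tsd_len` follows
#' the breakpoint-difference convention `entry_host - exit_host` (the
#' duplicated span itself contains `tsd_len + 1` bases).
#'
#' @param host_contig host contig name.
#' @param entry_host host coordinate of the last host base before the
#'   transgene (host-to-transgene junction).
#' @param exit_host host coordinate of the first host base after the
#'   transgene (transgene-to-host junction).
#' @param copies number of concatemer copies (>= 1).
#' @param entry_tg transgene coordinate of the first inserted base.
#' @param exit_tg transgene coordinate of the last inserted base.
#' @param unit_end_tg transgene coordinate at which each internal copy ends
#'   before looping back to position 1.
#' @param orientation `"forward"` or `"reverse"`.
#' @param zygosity `"het"` or `"hom"`.
#' @return object of class `insertion_truth` (a list).
#' @export
insertion_truth <- function(host_contig, entry_host, exit_host, copies,
                            entry_tg, exit_tg, unit_end_tg,
                            orientation = c("forward", "reverse"),
                            zygosity = c("het", "hom")) {
  orientation <- match.arg(orientation)
  zygosity <- match.arg(zygosity)
  if (copies < 1L) stop("copies must be >= 1")
  if (entry_host < exit_host)
    stop("entry_host must be >= exit_host (negative TSD not generated)")
  structure(list(host_contig = host_contig,
                 entry_host = as.integer(entry_host),
                 exit_host = as.integer(exit_host),
                 tsd_len = as.integer(entry_host - exit_host),
                 copies = as.integer(copies),
                 entry_tg = as.integer(entry_tg),
                 exit_tg = as.integer(exit_tg),
                 unit_end_tg = as.integer(unit_end_tg),
                 orientation = orientation,
                 zygosity = zygosity),
            class = "insertion_truth")
}

#' Closed-form length of the inserted transgene material
#'
#' First copy runs `entry_tg..unit_end_tg`, internal copies `1..unit_end_tg`,
#' the last copy `1..exit_tg`; a single copy runs `entry_tg..exit_tg`.
#'
#' @param truth an [insertion_truth()].
#' @return inserted length in nt.
#' @export
insert_span_nt <- function(truth) {
  with(truth, {
    if (copies == 1L) {
      if (entry_tg > exit_tg)
        stop("single-copy insertion requires entry_tg <= exit_tg")
      exit_tg - entry_tg + 1L
    } else {
      (unit_end_tg - entry_tg + 1L) +
        (copies - 2L) * unit_end_tg + exit_tg
    }
  })
}

#' Build the insertion haplotype sequence
#'
#' Pure string construction:
#' `host[1..entry_host] + concatemer + host[exit_host..end]`, where the
#' concatemer is the head-to-tail copy arrangement described in
#' [insertion_truth()], reverse-complemented as a block for reverse
#' orientation. Output length is
#' `host_length + tsd_len + 1 + insert_span_nt(truth)`.
#'
#' @param host host contig sequence.
#' @param truth an [insertion_truth()].
#' @param tg a [transgene_model()].
#' @return the inserted-haplotype sequence (character scalar).
#' @export
build_insertion_allele <- function(host, truth, tg) {
  L_host <- nchar(host)
  L_tg <- tg$length
  with(truth, {
    if (entry_host < 1L || entry_host > L_host ||
        exit_host < 1L || exit_host > L_host)
      stop("host coordinates out of range")
    if (any(c(entry_tg, exit_tg, unit_end_tg) < 1L) ||
        any(c(entry_tg, exit_tg, unit_end_tg) > L_tg))
      stop("transgene coordinates out of range")
  })
  s <- tg$sequence
  insert <- if (truth$copies == 1L) {
    if (truth$entry_tg > truth$exit_tg)
      stop("single-copy insertion requires entry_tg <= exit_tg")
    substr(s, truth$entry_tg, truth$exit_tg)
  } else {
    unit <- substr(s, 1L, truth$unit_end_tg)
    paste0(substr(s, truth$entry_tg, truth$unit_end_tg),
           strrep(unit, truth$copies - 2L),
           substr(s, 1L, truth$exit_tg))
  }
  if (truth$orientation == "reverse") insert <- revcomp(insert)
  paste0(substr(host, 1L, truth$entry_host),
         insert,
         substr(host, truth$exit_host, L_host))
}

# Make the ground-truth junction coordinates well-defined. A split-read
# junction is only defined up to (near-)homology between the joined
# sequences: a local ungapped aligner extends an anchor across the junction
# whenever the reference continuation scores net-positive against the read,
# shifting the observed clip boundary. For each junction and extension
# direction the generator therefore resamples reference-continuation bases
# until no prefix of the extension scores >= 0 under the mapper's default
# scoring, so the optimal clip boundary is exactly the simulated truth.
# Constraints interact through the target-site duplication, so they are
# iterated to a joint fixed point. Returns list(host, tg).
disambiguate_junctions <- function(host, tg, truth, match = 2L,
                                   mismatch = -3L, window = 16L) {
  chars_at <- function(s, idx) {
    idx <- idx[idx >= 1L & idx <= nchar(s)]
    if (!length(idx)) character(0)
    else substring(s, idx, idx)
  }
  # resample ref-side bases until no extension prefix scores >= 0;
  # returns possibly-modified ref string
  clean <- function(ref_str, ref_idx, read_bases) {
    n <- min(length(ref_idx), length(read_bases))
    if (n == 0L) return(list(s = ref_str, changed = FALSE))
    changed <- FALSE
    repeat {
      rb <- chars_at(ref_str, ref_idx[seq_len(n)])
      m <- length(rb)
      if (m == 0L) break
      sc <- ifelse(rb == read_bases[seq_len(m)], match, mismatch)
      pref <- cumsum(sc)
      bad <- which(pref >= 0)
      if (!length(bad)) break
      # resample the matched base closest to the junction inside the
      # offending prefix
      j <- which(sc[seq_len(bad[1])] == match)[1]
      i <- ref_idx[j]
      old <- substr(ref_str, i, i)
      substr(ref_str, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old),
                                      1L)
      changed <- TRUE
    }
    list(s = ref_str, changed = changed)
  }
  tgs <- tg$sequence
  tr <- truth
  W <- window
  for (pass in 1:100) {
    any_changed <- FALSE
    # entry junction, host anchor extending right past entry_host
    r <- clean(host, tr$entry_host + seq_len(W),
               chars_at(tgs, tr$entry_tg + 0:(W - 1L)))
    host <- r$s; any_changed <- any_changed || r$changed
    # entry junction, transgene anchor extending left before entry_tg
    r <- clean(tgs, tr$entry_tg - seq_len(W),
               chars_at(host, tr$entry_host - 0:(W - 1L)))
    tgs <- r$s; any_changed <- any_changed || r$changed
    # exit junction, transgene anchor extending right past exit_tg
    r <- clean(tgs, tr$exit_tg + seq_len(W),
               chars_at(host, tr$exit_host + 0:(W - 1L)))
    tgs <- r$s; any_changed <- any_changed || r$changed
    # exit junction, host anchor extending left before exit_host
    r <- clean(host, tr$exit_host - seq_len(W),
               chars_at(tgs, tr$exit_tg - 0:(W - 1L)))
    host <- r$s; any_changed <- any_changed || r$changed
    # tandem junction, anchor extending right past unit_end_tg
    if (tr$copies > 1L && tr$unit_end_tg < nchar(tgs)) {
      r <- clean(tgs, tr$unit_end_tg + seq_len(W),
                 chars_at(tgs, 0L + 1:W))
      tgs <- r$s; any_changed <- any_changed || r$changed
    }
    if (!any_changed) break
  }
  list(host = host, tg = transgene_model(tg$name, tgs, tg$features))
}

#' Simulate paired-end reads from a diploid genome
#'
#' Fragments are drawn uniformly along each haplotype with truncated-normal
#' lengths (clipped to `[read_len, 2 * frag_mean]`); each fragment is
#' sequenced from a random strand, read 2 being the reverse complement of the
#' fragment's 3' end. Substitution errors are i.i.d. per base; qualities are
#' constant. The origin of every pair is recorded for testing.
#'
#' @param haplotypes named character vector of haplotype sequences.
#' @param depth fold-coverage per haplotype (>= 0).
#' @param read_len read length in nt.
#' @param frag_mean,frag_sd fragment length model in nt.
#' @param err_rate per-base substitution probability.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame with columns id, seq1, seq2, qual1, qual2, hap,
#'   frag_start, frag_len, strand.
#' @export
simulate_reads <- function(haplotypes, depth, read_len = 100L,
                           frag_mean = 600L, frag_sd = 60L,
                           err_rate = 0.002, seed = NULL) {
  if (frag_mean < read_len) stop("frag_mean must be >= read_len")
  if (depth < 0) stop("depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(haplotypes))
  for (h in seq_along(haplotypes)) {
    hap <- haplotypes[[h]]
    L <- nchar(hap)
    n <- round(depth * L / (2 * read_len))
    if (n == 0) {
      out[[h]] <- NULL
      next
    }
    fl <- pmin(pmax(round(rnorm(n, frag_mean, frag_sd)), read_len),
               2L * frag_mean)
    fl <- pmin(fl, L)
    start <- floor(runif(n) * (L - fl + 1)) + 1
    left <- substring(hap, start, start + read_len - 1)
    right <- revcomp(substring(hap, start + fl - read_len, start + fl - 1))
    minus <- runif(n) < 0.5
    seq1 <- ifelse(minus, right, left)
    seq2 <- ifelse(minus, left, right)
    out[[h]] <- data.frame(
      id = sprintf("%s_frag%06d", names(haplotypes)[h], seq_len(n)),
      seq1 = seq1, seq2 = seq2,
      hap = names(haplotypes)[h],
      frag_start = as.integer(start), frag_len = as.integer(fl),
      strand = ifelse(minus, "-", "+"),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    pairs <- data.frame(id = character(0), seq1 = character(0),
                        seq2 = character(0), hap = character(0),
                        frag_start = integer(0), frag_len = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  if (err_rate > 0 && nrow(pairs)) {
    pairs$seq1 <- add_substitution_errors(pairs$seq1, err_rate)
    pairs$seq2 <- add_substitution_errors(pairs$seq2, err_rate)
  }
  pairs$qual1 <- rep(strrep("I", read_len), nrow(pairs))
  pairs$qual2 <- pairs$qual1
  pairs[c("id", "seq1", "seq2", "qual1", "qual2", "hap", "frag_start",
          "frag_len", "strand")]
}

# i.i.d. substitution errors at rate `rate`, uniform over the 3 other bases
add_substitution_errors <- function(reads, rate) {
  R <- nchar(reads[1])
  total <- length(reads) * R
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0) return(reads)
  flat <- sample.int(total, n_err)
  ridx <- (flat - 1L) %/% R + 1L
  pos <- (flat - 1L) %% R + 1L
  sub <- sample(1:3, n_err, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_err)) {
    old <- substr(reads[ridx[i]], pos[i], pos[i])
    new <- setdiff(bases, old)[sub[i]]
    if (is.na(new)) new <- bases[sub[i]]  # non-ACGT base: overwrite
    substr(reads[ridx[i]], pos[i], pos[i]) <- new
  }
  reads
}

#' Default simulated-study configuration
#'
#' The scaled "pds5b-like" fixture: a 200 kb host contig carrying a 12-copy
#' head-to-tail concatemer of a 6884 nt transgene on one haplotype, with the
#' junction geometry of the full-scale event (entry at transgene 4025, exit
#' at 2972, internal copies ending at 6850, a 10 nt target-site duplication
#' by the difference convention), sequenced at 12x per haplotype with 100 nt
#' paired-end reads, 600 +/- 60 nt fragments and 0.002 substitution errors.
#'
#' @param ... named overrides of any config entry.
#' @return named list of fixture, mapper, caller and estimator parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    host_contig = "host1", host_length = 200000L, gc_fraction = 0.42,
    tg_name = "transgene", tg_length = 6884L,
    entry_host = 100010L, exit_host = 100000L,
    copies = 12L, entry_tg = 4025L, exit_tg = 2972L, unit_end_tg = 6850L,
    orientation = "forward", zygosity = "het",
    depth = 12, read_len = 100L, frag_mean = 600L, frag_sd = 60L,
    err_rate = 0.002,
    k = 20L, match = 2L, mismatch = -3L,
    min_clip_len = 20L, min_support = 3L, slop = 3L,
    window = 500L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Build a simulated study with known ground truth
#'
#' Generates the host contig and transgene model, makes the junctions locally
#' unambiguous (see the methods vignette), constructs the diploid haplotypes
#' and simulates paired-end reads.
#'
#' @param config a [default_config()] list.
#' @param seed integer seed controlling every random choice.
#' @return list with host, tg (transgene model), truth, allele, haplotypes,
#'   reads, reference (named vector host + transgene), config, seed.
#' @export
make_fixture <- function(config = default_config(), seed = 1L) {
  set.seed(seed)
  host <- make_host_genome(config$host_length, config$gc_fraction)
  tg <- make_transgene_model(config$tg_length, config$tg_name,
                             gc_fraction = 0.5)
  truth <- insertion_truth(config$host_contig, config$entry_host,
                           config$exit_host, config$copies,
                           config$entry_tg, config$exit_tg,
                           config$unit_end_tg, config$orientation,
                           config$zygosity)
  fixed <- disambiguate_junctions(host, tg, truth)
  host <- fixed$host
  tg <- fixed$tg
  allele <- build_insertion_allele(host, truth, tg)
  haplotypes <- if (config$zygosity == "het")
    c(hapA = allele, hapB = host)
  else
    c(hapA = allele, hapB = allele)
  reads <- simulate_reads(haplotypes, config$depth, config$read_len,
                          config$frag_mean, config$frag_sd, config$err_rate)
  reference <- setNames(c(host, tg$sequence),
                        c(config$host_contig, config$tg_name))
  list(host = host, tg = tg, truth = truth, allele = allele,
       haplotypes = haplotypes, reads = reads, reference = reference,
       config = config, seed = seed)
}

#' Write a simulated study to disk
#'
#' Haplotypes and reference as FASTA, reads as paired FASTQ (`_1`/`_2`), and
#' the ground truth as JSON.
#'
#' @param fix a [make_fixture()] result.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of paths written.
#' @export
write_fixture <- function(fix, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    haplotypes = file.path(outdir, "haplotypes.fa"),
    reference = file.path(outdir, "reference.fa"),
    r1 = file.path(outdir, "reads_1.fq"),
    r2 = file.path(outdir, "reads_2.fq"),
    truth = file.path(outdir, "truth.json"))
  write_fasta(fix$haplotypes, paths["haplotypes"])
  write_fasta(fix$reference, paths["reference"])
  write_fastq(paste0(fix$reads$id, "/1"), fix$reads$seq1, fix$reads$qual1,
              paths["r1"])
  write_fastq(paste0(fix$reads$id, "/2"), fix$reads$seq2, fix$reads$qual2,
              paths["r2"])
  write_json_report(unclass(fix$truth), paths["truth"])
  invisible(paths)
}
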