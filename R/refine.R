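#' Refine a transgene model from read pileups
#'
#' One pass of the iterative model-refinement loop: at every transgene
#' position with depth >= `min_depth`, a non-reference base reaching a
#' pileup fraction >= `min_fraction` replaces the model base. The caller
#' loops map -> refine (see [iterate_refinement()]) until an iteration
#' changes zero positions. Only substitutions are corrected; length-changing
#' edits are the business of [diff_models()].
#'
#' @param alignments alignment data.frame produced against `model`.
#' @param model the [transgene_model()] the alignments were made against.
#' @param min_depth minimum pileup depth to consider a position.
#' @param min_fraction minimum non-reference base fraction to edit.
#' @return list with `model` (updated), `n_changed`, `converged`.
#' @export
refine_model <- function(alignments, model, min_depth = 5L,
                         min_fraction = 0.8) {
  on_tg <- !is.na(alignments$pos) & alignments$rname == model$name
  aln <- alignments[on_tg, , drop = FALSE]
  counts <- cpp_pileup(aln$seq, aln$pos, aln$clip_left, aln$m_len,
                       model$length)
  depth <- colSums(counts)
  if (all(depth == 0)) {
    warning("zero coverage everywhere on '", model$name,
            "': model unchanged")
    return(list(model = model, n_changed = 0L, converged = TRUE))
  }
  bases <- c("A", "C", "G", "T")
  top <- max.col(t(counts[1:4, , drop = FALSE]), ties.method = "first")
  top_n <- counts[cbind(top, seq_len(model$length))]
  ref <- strsplit(model$sequence, "")[[1]]
  edit <- depth >= min_depth &
    top_n / pmax(depth, 1L) >= min_fraction &
    bases[top] != ref
  n_changed <- sum(edit)
  if (n_changed > 0) {
    ref[edit] <- bases[top[edit]]
    model <- transgene_model(model$name, paste(ref, collapse = ""),
                             model$features)
  }
  list(model = model, n_changed = as.integer(n_changed),
       converged = n_changed == 0L)
}

#' Iterate map -> refine until the model converges
#'
#' @param pairs read pairs (see [map_pairs()]).
#' @param host_contigs named character vector of non-transgene reference
#'   contigs (may be empty).
#' @param model starting [transgene_model()].
#' @param k,match,mismatch mapper parameters.
#' @param min_depth,min_fraction consensus thresholds (see [refine_model()]).
#' @param max_iter iteration cap.
#' @return list with `model`, `iterations`, `converged`.
#' @export
iterate_refinement <- function(pairs, host_contigs, model, k = 20L,
                               match = 2L, mismatch = -3L, min_depth = 5L,
                               min_fraction = 0.8, max_iter = 5L) {
  converged <- FALSE
  it <- 0L
  while (it < max_iter && !converged) {
    it <- it + 1L
    ref <- c(host_contigs, setNames(model$sequence, model$name))
    idx <- index_reference(ref, k)
    mp <- map_pairs(pairs, idx, match, mismatch)
    res <- refine_model(mp$alignments, model, min_depth, min_fraction)
    model <- res$model
    converged <- res$converged
  }
  list(model = model, iterations = it, converged = converged)
}

# match +1 / mismatch -2 over {A,C,G,T}; N scores 0 against anything
diff_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Diff a refined model against an external reference sequence
#'
#' Globally aligns the two sequences (match +1, mismatch -2; a gap of
#' length L costs 3 + L, i.e. -4 to open and -1 to extend) and reports the
#' edits that turn the reference into the model, on reference coordinates.
#' Adjacent same-type edits are merged. Insertions are anchored to the
#' reference base after which they occur (0 for an insertion before the
#' first base).
#'
#' @param model a [transgene_model()] or a plain sequence string.
#' @param reference comparison sequence string.
#' @return data.frame of variants: kind (insertion/deletion/substitution),
#'   position (reference coordinate), length, sequence.
#' @export
diff_models <- function(model, reference) {
  mseq <- if (inherits(model, "transgene_model")) model$sequence else model
  if (nchar(mseq) == 0 || nchar(reference) == 0)
    stop("both sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    pattern = mseq, subject = reference, type = "global",
    substitutionMatrix = diff_submat(), gapOpening = 3, gapExtension = 1)
  # aligned-range strings exclude end overhangs; handle those explicitly
  ps <- Biostrings::start(Biostrings::pattern(pa))
  pe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  se <- Biostrings::end(Biostrings::subject(pa))
  out <- list()
  add <- function(kind, position, sequence)
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind, position = as.integer(position),
      length = nchar(sequence), sequence = sequence,
      stringsAsFactors = FALSE)
  if (ss > 1) add("deletion", 1L, substr(reference, 1L, ss - 1L))
  if (ps > 1) add("insertion", ss - 1L, substr(mseq, 1L, ps - 1L))
  p <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  kind <- ifelse(s == "-", "insertion",
                 ifelse(p == "-", "deletion",
                        ifelse(p == s, "match", "substitution")))
  refpos <- cumsum(s != "-") + (ss - 1L)  # reference coordinate per column
  runs <- rle(kind)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in seq_along(runs$values)) {
    kd <- runs$values[i]
    if (kd == "match") next
    cols <- starts[i]:ends[i]
    seq_txt <- paste((if (kd == "deletion") s else p)[cols], collapse = "")
    # for insertions refpos has not advanced, so this is the preceding base
    add(kd, refpos[starts[i]], seq_txt)
  }
  if (pe < nchar(mseq)) add("insertion", se, substring(mseq, pe + 1L))
  if (se < nchar(reference)) add("deletion", se + 1L,
                                 substring(reference, se + 1L))
  if (!length(out))
    return(data.frame(kind = character(0), position = integer(0),
                      length = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$kind), , drop = FALSE]
  # merge contiguous same-kind edits into one variant
  i <- 1L
  while (i < nrow(res)) {
    a <- res[i, ]; b <- res[i + 1L, ]
    contiguous <- a$kind == b$kind &&
      ((a$kind == "insertion" && a$position == b$position) ||
       (a$kind != "insertion" && b$position == a$position + a$length))
    if (contiguous) {
      res$sequence[i] <- paste0(a$sequence, b$sequence)
      res$length[i] <- a$length + b$length
      res <- res[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(res) <- NULL
  res
}

#' Apply a variant list to a reference sequence
#'
#' Inverse of [diff_models()]: applying the variants it reports to the
#' reference reconstructs the model exactly.
#'
#' @param reference sequence string.
#' @param variants data.frame as returned by [diff_models()].
#' @return edited sequence string.
#' @export
apply_variants <- function(reference, variants) {
  chars <- strsplit(reference, "")[[1]]
  keep <- rep(TRUE, length(chars))
  repl <- chars
  inserts <- rep("", length(chars) + 1L)  # inserts[i+1] = after ref base i
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (v$kind == "substitution") {
        idx <- v$position:(v$position + v$length - 1L)
        repl[idx] <- strsplit(v$sequence, "")[[1]]
      } else if (v$kind == "deletion") {
        keep[v$position:(v$position + v$length - 1L)] <- FALSE
      } else {
        inserts[v$position + 1L] <- paste0(inserts[v$position + 1L],
                                           v$sequence)
      }
    }
  }
  body <- ifelse(keep, repl, "")
  paste0(inserts[1],
         paste(paste0(body, inserts[-1]), collapse = ""))
}

#' Write / read a variant table as TSV
#'
#' @param variants data.frame from [diff_models()].
#' @param path file path.
#' @export
write_variants <- function(variants, path) write_tsv(variants, path)

#' @rdname write_variants
#' @export
read_variants <- function(path) read_tsv(path)
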