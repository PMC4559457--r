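# Split-read fusion calling: cluster soft-clipped alignments, realign the
# clipped consensus sequences against the full reference, and join the two
# loci of each junction into a fusion call.

# one record per qualifying soft clip: the boundary it abuts and its sequence
soft_clip_records <- function(alignments, min_clip_len) {
  aln <- alignments[!is.na(alignments$pos), , drop = FALSE]
  if (nrow(aln) == 0)
    return(data.frame(ref_name = character(0), boundary = integer(0),
                      side = character(0), clip = character(0),
                      stringsAsFactors = FALSE))
  rbind(
    with(aln[aln$clip_left >= min_clip_len, , drop = FALSE],
         data.frame(ref_name = rname, boundary = pos,
                    side = rep("left", length(pos)),
                    clip = substr(seq, 1L, clip_left),
                    stringsAsFactors = FALSE)),
    with(aln[aln$clip_right >= min_clip_len, , drop = FALSE],
         data.frame(ref_name = rname, boundary = pos + m_len - 1L,
                    side = rep("right", length(pos)),
                    clip = substr(seq, clip_left + m_len + 1L, nchar(seq)),
                    stringsAsFactors = FALSE)))
}

clip_consensus <- function(clips, side) {
  if (side == "left")
    clips <- vapply(strsplit(clips, ""), function(x)
      paste(rev(x), collapse = ""), "")
  n <- max(nchar(clips))
  mat <- matrix(NA_character_, length(clips), n)
  sp <- strsplit(clips, "")
  for (i in seq_along(sp)) mat[i, seq_along(sp[[i]])] <- sp[[i]]
  cons <- apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    tab <- table(col)
    top <- tab[tab == max(tab)]
    if (length(top) > 1) "N" else names(top)  # majority; ties -> N
  })
  out <- paste(cons, collapse = "")
  if (side == "left")
    out <- paste(rev(strsplit(out, "")[[1]]), collapse = "")
  out
}

#' Cluster soft-clipped alignments at shared boundaries
#'
#' Reads whose soft clip is at least `min_clip_len` nt are grouped by
#' (contig, clip boundary within `slop`, side). The boundary of a left-side
#' cluster is the first aligned base (the clip precedes it); of a right-side
#' cluster the last aligned base (the clip follows it). The cluster
#' consensus is a per-column majority of the clipped sequences, anchored at
#' the junction; ties give N.
#'
#' @param alignments alignment data.frame (see [map_pairs()]).
#' @param min_clip_len minimum clip length in nt.
#' @param min_support minimum reads per cluster.
#' @param slop boundary tolerance in nt.
#' @return data.frame: ref_name, position (modal boundary), side, support,
#'   consensus_clip.
#' @export
collect_clusters <- function(alignments, min_clip_len = 20L,
                             min_support = 3L, slop = 3L) {
  empty <- data.frame(ref_name = character(0), position = integer(0),
                      side = character(0), support = integer(0),
                      consensus_clip = character(0),
                      stringsAsFactors = FALSE)
  recs <- soft_clip_records(alignments, min_clip_len)
  if (nrow(recs) == 0) return(empty)
  out <- list()
  for (key in split(recs, paste(recs$ref_name, recs$side))) {
    key <- key[order(key$boundary), , drop = FALSE]
    grp <- cumsum(c(1L, diff(key$boundary) > slop))
    for (g in split(key, grp)) {
      if (nrow(g) < min_support) next
      tab <- table(g$boundary)
      modal <- as.integer(names(tab)[which.max(tab)])
      out[[length(out) + 1L]] <- data.frame(
        ref_name = g$ref_name[1], position = modal, side = g$side[1],
        support = nrow(g),
        consensus_clip = clip_consensus(g$clip, g$side[1]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$ref_name, res$position, res$side), , drop = FALSE]
}

# Microhomology between the 5' locus (ref_a, ends at pos_a, forward) and the
# 3' locus (ref_b, starts at pos_b, forward): bases assignable to either
# side. The junction is reported at the leftmost consistent position and the
# homologous bases once.
junction_microhomology <- function(seq_a, pos_a, seq_b, pos_b) {
  k_left <- 0L
  while (pos_a - k_left >= 1L && pos_b - 1L - k_left >= 1L &&
         substr(seq_a, pos_a - k_left, pos_a - k_left) ==
         substr(seq_b, pos_b - 1L - k_left, pos_b - 1L - k_left))
    k_left <- k_left + 1L
  k_right <- 0L
  while (pos_a + 1L + k_right <= nchar(seq_a) &&
         pos_b + k_right <= nchar(seq_b) &&
         substr(seq_a, pos_a + 1L + k_right, pos_a + 1L + k_right) ==
         substr(seq_b, pos_b + k_right, pos_b + k_right))
    k_right <- k_right + 1L
  mh <- if (k_left + k_right > 0)
    substr(seq_b, pos_b - k_left, pos_b + k_right - 1L)
  else ""
  list(mh = mh, pos_a = pos_a - k_left, pos_b = pos_b - k_left)
}

empty_fusions <- function() {
  data.frame(ref_a = character(0), pos_a = integer(0),
             orient_a = character(0), ref_b = character(0),
             pos_b = integer(0), orient_b = character(0),
             support = integer(0), microhomology = character(0),
             untemplated = character(0), stringsAsFactors = FALSE)
}

#' Realign clipped consensus sequences and emit fusions
#'
#' Each cluster consensus is locally aligned to the full reference; a hit
#' joins the cluster boundary to the realigned locus. Every fusion is
#' oriented 5' to 3' along the fused sequence: `(ref_a, pos_a)` is the last
#' base of the upstream side and `(ref_b, pos_b)` the first base of the
#' downstream side. An unaligned clip prefix that matches neither side is
#' reported as untemplated sequence; microhomology (bases assignable to
#' either side) is computed for forward-forward junctions and the junction
#' placed at its leftmost consistent position.
#'
#' @param clusters data.frame from [collect_clusters()].
#' @param reference named character vector (host contigs + transgene).
#' @param k_realign seed length for clip realignment.
#' @param match,mismatch alignment scoring.
#' @return list with `fusions` (data.frame) and `unresolved` (clusters whose
#'   consensus realigned nowhere).
#' @export
realign_clips <- function(clusters, reference, k_realign = 14L,
                          match = 2L, mismatch = -3L) {
  if (nrow(clusters) == 0)
    return(list(fusions = empty_fusions(), unresolved = clusters))
  idx <- index_reference(reference, k_realign)
  hits <- align_batch(clusters$consensus_clip, idx, match, mismatch,
                      ids = sprintf("cluster%03d", seq_len(nrow(clusters))))
  resolved <- !is.na(hits$pos)
  out <- list()
  for (i in which(resolved)) {
    cl <- clusters[i, ]
    ht <- hits[i, ]
    clip_len <- nchar(cl$consensus_clip)
    if (cl$side == "right") {
      # clip continues 3' of the boundary; its start abuts the junction
      un_len <- if (ht$strand == "+") ht$clip_left else ht$clip_right
      a <- list(ref = cl$ref_name, pos = cl$position, orient = "+")
      b <- if (ht$strand == "+")
        list(ref = ht$rname, pos = ht$pos, orient = "+")
      else
        list(ref = ht$rname, pos = ht$pos + ht$m_len - 1L, orient = "-")
      untemplated <- if (un_len > 0)
        substr(cl$consensus_clip, 1L, un_len) else ""
    } else {
      # clip precedes the boundary; its end abuts the junction
      un_len <- if (ht$strand == "+") ht$clip_right else ht$clip_left
      b <- list(ref = cl$ref_name, pos = cl$position, orient = "+")
      a <- if (ht$strand == "+")
        list(ref = ht$rname, pos = ht$pos + ht$m_len - 1L, orient = "+")
      else
        list(ref = ht$rname, pos = ht$pos, orient = "-")
      untemplated <- if (un_len > 0)
        substr(cl$consensus_clip, clip_len - un_len + 1L, clip_len) else ""
    }
    mh <- ""
    if (untemplated == "" && a$orient == "+" && b$orient == "+") {
      m <- junction_microhomology(reference[[a$ref]], a$pos,
                                  reference[[b$ref]], b$pos)
      mh <- m$mh
      a$pos <- m$pos_a
      b$pos <- m$pos_b
    }
    out[[length(out) + 1L]] <- data.frame(
      ref_a = a$ref, pos_a = a$pos, orient_a = a$orient,
      ref_b = b$ref, pos_b = b$pos, orient_b = b$orient,
      support = cl$support, microhomology = mh, untemplated = untemplated,
      stringsAsFactors = FALSE)
  }
  fus <- if (length(out)) do.call(rbind, out) else empty_fusions()
  list(fusions = fus, unresolved = clusters[!resolved, , drop = FALSE])
}

# Merge fusion calls that describe the same junction: reciprocal clusters
# from the two flanks, and calls shifted along the junction by (near-)
# homologous anchor extension. Two calls are the same junction when refs and
# orientations agree, their diagonals (pos_a - pos_b for forward-forward,
# pos_a + pos_b when the downstream side is inverted) agree within `slop`,
# and the positional offset is at most `coherence`. Support is summed;
# coordinates come from the best-supported member.
merge_fusions <- function(fus, slop = 3L, coherence = 25L) {
  if (nrow(fus) <= 1) return(fus)
  fus <- fus[order(-fus$support, fus$ref_a, fus$pos_a, fus$pos_b), ,
             drop = FALSE]
  diag_of <- function(f)
    if (f$orient_b == "-") f$pos_a + f$pos_b else f$pos_a - f$pos_b
  group <- integer(nrow(fus))
  reps <- integer(0)  # row index of first member of each group
  for (i in seq_len(nrow(fus))) {
    f <- fus[i, ]
    for (j in seq_along(reps)) {
      g <- fus[reps[j], ]
      if (f$ref_a == g$ref_a && f$ref_b == g$ref_b &&
          f$orient_a == g$orient_a && f$orient_b == g$orient_b &&
          abs(diag_of(f) - diag_of(g)) <= slop &&
          abs(f$pos_a - g$pos_a) <= coherence) {
        group[i] <- j
        break
      }
    }
    if (group[i] == 0L) {
      reps <- c(reps, i)
      group[i] <- length(reps)
    }
  }
  kept <- fus[0, ]
  for (j in seq_along(reps)) {
    members <- fus[group == j, , drop = FALSE]
    # coordinates by support-weighted vote over identical boundary pairs
    key <- paste(members$pos_a, members$pos_b)
    votes <- tapply(members$support, key, sum)
    win <- members[key == names(votes)[which.max(votes)], , drop = FALSE][1, ]
    win$support <- sum(members$support)
    kept <- rbind(kept, win)
  }
  kept
}

# Junction support recount: clusters below min_support on one side of a
# junction are dropped before merging, which would undercount split reads at
# asymmetric junctions; once a fusion is called, every qualifying clip
# abutting either of its boundaries supports it. Forward-forward fusions
# only; inverted fusions keep their cluster-sum support.
recount_support <- function(fusions, alignments, support_clip_len, slop,
                            support_slop = 10L) {
  if (nrow(fusions) == 0) return(fusions)
  recs <- soft_clip_records(alignments, support_clip_len)
  w <- max(slop, support_slop)
  for (i in seq_len(nrow(fusions))) {
    f <- fusions[i, ]
    if (f$orient_a != "+" || f$orient_b != "+") next
    at_a <- recs$ref_name == f$ref_a & recs$side == "right" &
      abs(recs$boundary - f$pos_a) <= w
    at_b <- recs$ref_name == f$ref_b & recs$side == "left" &
      abs(recs$boundary - f$pos_b) <= w
    fusions$support[i] <- sum(at_a | at_b)
  }
  fusions
}

#' Call fusions from soft-clipped alignments
#'
#' Composition of [collect_clusters()] and [realign_clips()] with reciprocal
#' junction calls merged. Clusters are collected without a support floor so
#' that a junction whose split reads are unevenly divided between its two
#' flanks is not lost; `min_support` is applied to the merged per-junction
#' total. Each surviving fusion's support is then recounted as the number
#' of soft clips of at least `support_clip_len` nt abutting either of its
#' boundaries (discovery needs clips long enough to realign; support only
#' needs an unambiguous boundary match). Output is sorted by support
#' (descending), then coordinates.
#'
#' @inheritParams collect_clusters
#' @inheritParams realign_clips
#' @param support_clip_len minimum clip length for support recounting.
#' @return fusion data.frame (see [realign_clips()]).
#' @export
call_fusions <- function(alignments, reference, min_clip_len = 20L,
                         min_support = 3L, slop = 3L, k_realign = 14L,
                         match = 2L, mismatch = -3L,
                         support_clip_len = 8L) {
  clusters <- collect_clusters(alignments, min_clip_len,
                               min_support = 1L, slop = slop)
  res <- realign_clips(clusters, reference, k_realign, match, mismatch)
  fus <- merge_fusions(res$fusions, slop)
  fus <- recount_support(fus, alignments, support_clip_len, slop)
  fus <- fus[fus$support >= min_support, , drop = FALSE]
  fus <- fus[order(-fus$support, fus$ref_a, fus$pos_a, fus$ref_b,
                   fus$pos_b), , drop = FALSE]
  rownames(fus) <- NULL
  fus
}

#' Write fusions as TSV and BEDPE
#'
#' @param fusions fusion data.frame.
#' @param path output path (TSV) or BEDPE path.
#' @export
write_fusions <- function(fusions, path) write_tsv(fusions, path)

#' @rdname write_fusions
#' @export
write_fusions_bedpe <- function(fusions, path) {
  bedpe <- data.frame(
    fusions$ref_a, fusions$pos_a - 1L, fusions$pos_a,
    fusions$ref_b, fusions$pos_b - 1L, fusions$pos_b,
    sprintf("fusion%03d", seq_len(nrow(fusions))),
    fusions$support, fusions$orient_a, fusions$orient_b)
  write.table(bedpe, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
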