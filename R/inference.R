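# Turning fusion calls and depth profiles into a reconstructed insertion
# allele: fusion classification, TSD/orientation geometry, concatemer copy
# number, and annotation against gene structure.

#' Classify fusions by their relation to the transgene
#'
#' @param fusions fusion data.frame (see [call_fusions()]).
#' @param transgene_name name of the transgene contig.
#' @return list of data.frames: `self_fusions` (both loci on the transgene,
#'   the tandem concatemer junction), `entry_fusions` (host to transgene),
#'   `exit_fusions` (transgene to host), `unrelated`.
#' @export
classify_fusions <- function(fusions, transgene_name) {
  a_tg <- fusions$ref_a == transgene_name
  b_tg <- fusions$ref_b == transgene_name
  list(self_fusions = fusions[a_tg & b_tg, , drop = FALSE],
       entry_fusions = fusions[!a_tg & b_tg, , drop = FALSE],
       exit_fusions = fusions[a_tg & !b_tg, , drop = FALSE],
       unrelated = fusions[!a_tg & !b_tg, , drop = FALSE])
}

#' Reconstruct the insertion allele geometry from fusions
#'
#' The entry fusion supplies the host entry coordinate and the transgene
#' coordinate of the first inserted base; the exit fusion the last inserted
#' base and the host exit coordinate; the tandem (self) fusion, when
#' present, the coordinate at which internal copies end. The target-site
#' duplication length follows the breakpoint-difference convention
#' `entry_host - exit_host`; `tsd_seq` is the inclusive duplicated span
#' (`tsd_len + 1` bases). A negative difference is reported as a deletion at
#' the insertion site (tsd_len 0, flagged).
#'
#' @param entry,exit single-row fusion data.frames.
#' @param self_fusion single-row fusion data.frame or `NULL`.
#' @param host_seq host contig sequence (for `tsd_seq`), or `NULL`.
#' @return object of class `insertion_allele`: geometry fields plus empty
#'   copy-number slots (filled by the estimators).
#' @export
reconstruct_insertion <- function(entry, exit, self_fusion = NULL,
                                  host_seq = NULL) {
  if (entry$ref_a != exit$ref_b) {
    warning("entry and exit fusions on different host contigs (",
            entry$ref_a, " vs ", exit$ref_b, "): possible multi-site ",
            "integration, no single allele emitted")
    return(NULL)
  }
  entry_host <- entry$pos_a
  exit_host <- exit$pos_b
  tsd_len <- entry_host - exit_host
  flags <- character(0)
  if (tsd_len < 0L) {
    flags <- "deletion_at_insertion_site"
    tsd_len <- 0L
  }
  orientation <- if (entry$orient_b == "+" && exit$orient_a == "+")
    "forward"
  else if (entry$orient_b == "-" && exit$orient_a == "-")
    "reverse"
  else "conflicting"
  tsd_seq <- if (!is.null(host_seq) && !length(flags))
    substr(host_seq, exit_host, entry_host)
  else ""
  structure(list(
    host_contig = entry$ref_a,
    entry_host = entry_host, exit_host = exit_host,
    tsd_len = as.integer(tsd_len), tsd_seq = tsd_seq,
    entry_tg = entry$pos_b, exit_tg = exit$pos_a,
    unit_end_tg = if (!is.null(self_fusion) && nrow(self_fusion))
      self_fusion$pos_a[1] else NA_integer_,
    orientation = orientation,
    copies_depth = NA_real_, copies_junction = NA_real_,
    total_insert_len = NA_integer_,
    flags = flags), class = "insertion_allele")
}

#' @export
print.insertion_allele <- function(x, ...) {
  cat("insertion allele on ", x$host_contig, ": entry ", x$entry_host,
      " (tg:", x$entry_tg, "), exit ", x$exit_host, " (tg:", x$exit_tg,
      "), TSD ", x$tsd_len, " nt, orientation ", x$orientation, "\n",
      sep = "")
  if (!is.na(x$copies_depth))
    cat("  copies: depth ", round(x$copies_depth, 2), ", junction ",
        round(x$copies_junction, 2), "\n", sep = "")
  invisible(x)
}

#' Windowed read-depth profile
#'
#' Mean depth per non-overlapping tiling window: aligned M bases overlapping
#' the window divided by the window length.
#'
#' @param alignments alignment data.frame.
#' @param ref_lengths named integer vector of contig lengths.
#' @param window window size in nt (>= 1).
#' @return data.frame: ref_name, start, end, depth.
#' @export
depth_profile <- function(alignments, ref_lengths, window = 500L) {
  if (window < 1L) stop("window must be >= 1")
  out <- list()
  for (ctg in names(ref_lengths)) {
    L <- ref_lengths[[ctg]]
    sel <- !is.na(alignments$pos) & alignments$rname == ctg
    ir <- IRanges::IRanges(start = alignments$pos[sel],
                           width = alignments$m_len[sel])
    ir <- IRanges::restrict(ir, start = 1L, end = L)
    cov <- IRanges::coverage(ir, width = L)
    starts <- seq.int(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    v <- IRanges::Views(cov, start = starts, end = ends)
    out[[ctg]] <- data.frame(ref_name = ctg, start = starts, end = ends,
                             depth = IRanges::viewMeans(v),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window") <- as.integer(window)
  res
}

#' Estimate concatemer copy number from read depth
#'
#' The per-haplotype depth `h` is half the median host window depth
#' (host windows within `exclude_flank` of the insertion site are
#' excluded, as are windows beyond the transgene unit). The naive estimate
#' is the median transgene window depth over `h` (over `2h` for a
#' homozygote); because the terminal copies of a concatemer are truncated,
#' this ratio measures mean copy multiplicity (about N-1 when no transgene
#' base lies in all N copies). When the junction geometry recovered from the
#' fusions is supplied, the estimator instead inverts the exact expected
#' aligned-base total
#' `T = h * ((unit_end - entry + 1) + (N - 2) * unit_end + exit)` for N,
#' which is unbiased for the true copy count.
#'
#' @param profile a [depth_profile()].
#' @param transgene_name transgene contig name.
#' @param zygosity `"het"` (insertion on one haplotype) or `"hom"`.
#' @param geometry optional list/`insertion_allele` with entry_tg, exit_tg,
#'   unit_end_tg.
#' @param insertion_site optional list(contig, pos) of the insertion, whose
#'   surrounding host windows are excluded from `h`.
#' @param exclude_flank half-width of the host exclusion zone in nt.
#' @return list: copies_depth (geometry-corrected when possible),
#'   copies_naive, h (per-haplotype depth), t (median transgene depth),
#'   method.
#' @export
estimate_copy_number <- function(profile, transgene_name,
                                 zygosity = c("het", "hom"),
                                 geometry = NULL, insertion_site = NULL,
                                 exclude_flank = 2000L) {
  zygosity <- match.arg(zygosity)
  host <- profile[profile$ref_name != transgene_name, , drop = FALSE]
  if (!is.null(insertion_site)) {
    near <- host$ref_name == insertion_site$contig &
      host$end >= insertion_site$pos - exclude_flank &
      host$start <= insertion_site$pos + exclude_flank
    host <- host[!near, , drop = FALSE]
  }
  tg <- profile[profile$ref_name == transgene_name, , drop = FALSE]
  if (nrow(host) == 0 || nrow(tg) == 0)
    stop("profile must cover both host contig(s) and the transgene")
  h <- median(host$depth) / 2
  if (h == 0) stop("zero host depth: copy-number estimation impossible")
  ploidy <- if (zygosity == "het") 1 else 2
  tg_use <- tg
  if (!is.null(geometry) && !is.na(geometry$unit_end_tg))
    tg_use <- tg[tg$start <= geometry$unit_end_tg, , drop = FALSE]
  t_med <- median(tg_use$depth)
  naive <- t_med / (ploidy * h)
  if (is.null(geometry) || is.na(geometry$unit_end_tg)) {
    return(list(copies_depth = naive, copies_naive = naive, h = h,
                t = t_med, method = "median_ratio"))
  }
  total <- sum(tg$depth * (tg$end - tg$start + 1))
  first_len <- geometry$unit_end_tg - geometry$entry_tg + 1
  last_len <- geometry$exit_tg
  copies <- (total / (ploidy * h) - first_len - last_len) /
    geometry$unit_end_tg + 2
  list(copies_depth = copies, copies_naive = naive, h = h, t = t_med,
       method = "geometry_corrected")
}

#' Estimate copy number from junction read support
#'
#' A concatemer of N copies has N-1 tandem junctions per haplotype against
#' one entry and one exit junction, so
#' `copies = self_support / mean(entry_support, exit_support) + 1`.
#'
#' The host-junction supports are small counts (a single junction site
#' each), so the plain ratio inherits the upward bias of `E[1/x]`; with
#' `correction = TRUE` the pooled denominator gets the standard add-one
#' Poisson ratio correction, `copies = 2 * self / (entry + exit + 1) + 1`,
#' which is nearly unbiased at the read depths this pipeline works at.
#'
#' @param self_support,entry_support,exit_support split-read support counts.
#' @param correction apply the small-sample ratio correction.
#' @return copies estimate (`NA` when host-junction support is zero).
#' @export
junction_copy_estimate <- function(self_support, entry_support,
                                   exit_support, correction = FALSE) {
  if (entry_support <= 0 || exit_support <= 0) {
    warning("zero host-junction support: junction copy estimate ",
            "not available")
    return(NA_real_)
  }
  denom <- if (correction)
    (entry_support + exit_support + 1) / 2
  else
    mean(c(entry_support, exit_support))
  self_support / denom + 1
}

#' Total inserted length of the concatemer
#'
#' Exact sum of the first copy (`entry_tg..unit_end_tg`), internal copies
#' (`1..unit_end_tg` each) and the last copy (`1..exit_tg`); for a single
#' copy, `entry_tg..exit_tg`. The simple reporting convention
#' `copies * tg_length` is returned alongside.
#'
#' @param allele an `insertion_allele` or [insertion_truth()] (geometry
#'   fields).
#' @param copies integer copy number.
#' @param tg_length full transgene model length for the simple convention
#'   (`NA` omits it).
#' @return list: exact_nt, simple_nt.
#' @export
total_insert_length <- function(allele, copies, tg_length = NA) {
  exact <- if (copies == 1L) {
    allele$exit_tg - allele$entry_tg + 1
  } else {
    (allele$unit_end_tg - allele$entry_tg + 1) +
      (copies - 2) * allele$unit_end_tg + allele$exit_tg
  }
  list(exact_nt = exact,
       simple_nt = if (is.na(tg_length)) NA_real_ else copies * tg_length)
}

#' Annotate the insertion position against gene structure
#'
#' Finds the nearest annotated feature on the insertion's host contig and
#' reports the distance and relation. Distances are measured on the
#' feature's strand from the host entry coordinate: for a + strand feature
#' starting downstream of the insertion, distance = feature_start -
#' entry_host and the insertion is upstream of it.
#'
#' @param allele an `insertion_allele` (or any list with host_contig and
#'   entry_host).
#' @param annotation data.frame from [read_bed()] (1-based inclusive).
#' @return list: feature, distance (nt), relation (upstream / downstream /
#'   inside); `NA` fields when the annotation is empty.
#' @export
annotate_position <- function(allele, annotation) {
  ann <- annotation[annotation$chrom == allele$host_contig, , drop = FALSE]
  if (nrow(ann) == 0)
    return(list(feature = NA_character_, distance = NA_integer_,
                relation = NA_character_))
  p <- allele$entry_host
  inside <- p >= ann$start & p <= ann$end
  dist <- ifelse(inside, 0L, pmin(abs(ann$start - p), abs(ann$end - p)))
  i <- which.min(dist)
  if (inside[i])
    return(list(feature = ann$name[i], distance = 0L, relation = "inside"))
  plus <- is.na(ann$strand[i]) | ann$strand[i] != "-"
  before <- p < ann$start[i]
  relation <- if (plus == before) "upstream" else "downstream"
  d <- if (before) ann$start[i] - p else p - ann$end[i]
  list(feature = ann$name[i], distance = as.integer(d), relation = relation)
}
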