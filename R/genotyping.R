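# In-silico junction PCR genotyping and Mendelian segregation statistics.

#' Construct a primer
#'
#' @param name identifier.
#' @param sequence 15-30 nt over `{A,C,G,T}` written 5' to 3'.
#' @param role `"forward"` or `"reverse"`.
#' @return object of class `primer` (a list).
#' @export
primer <- function(name, sequence, role = c("forward", "reverse")) {
  role <- match.arg(role)
  if (grepl("[^ACGT]", sequence)) stop("primer must be over {A,C,G,T}")
  if (nchar(sequence) < 15L || nchar(sequence) > 30L)
    stop("primer length must be 15-30 nt")
  structure(list(name = name, sequence = sequence, role = role),
            class = "primer")
}

#' Find primer annealing sites on a template
#'
#' Reports every position where the primer (plus strand) or its reverse
#' complement (minus strand, i.e. annealing to the reverse strand) matches
#' the template with at most `max_mismatch` substitutions. The primer's
#' 3'-terminal base must match exactly - extension specificity is what makes
#' a junction-spanning primer discriminate the insertion allele.
#'
#' @param template template sequence string.
#' @param pr a [primer()].
#' @param max_mismatch maximum substitutions elsewhere in the primer.
#' @return data.frame: position (1-based start of the matched span on the
#'   template), strand, mismatches.
#' @export
find_primer_sites <- function(template, pr, max_mismatch = 1L) {
  if (nchar(pr$sequence) >= nchar(template))
    stop("primer must be shorter than template")
  tmpl <- Biostrings::DNAString(template)
  hits <- function(query, strand) {
    m <- Biostrings::matchPattern(query, tmpl, max.mismatch = max_mismatch)
    if (length(m) == 0)
      return(data.frame(position = integer(0), strand = character(0),
                        mismatches = integer(0), stringsAsFactors = FALSE))
    frag <- as.character(m)
    q <- strsplit(query, "")[[1]]
    mm <- vapply(strsplit(frag, ""), function(x) sum(x != q), 1L)
    # 3' base: last primer base on +, first template base of the span on -
    three_prime_ok <- if (strand == "+")
      substr(frag, length(q), length(q)) == q[length(q)]
    else
      substr(frag, 1L, 1L) == q[1L]
    keep <- three_prime_ok & mm <= max_mismatch
    data.frame(position = IRanges::start(m)[keep],
               strand = rep(strand, sum(keep)),
               mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  rbind(hits(pr$sequence, "+"), hits(revcomp(pr$sequence), "-"))
}

#' Predict PCR amplicons on a set of templates
#'
#' Multiplex product logic: every plus-strand primer hit paired with a
#' downstream minus-strand hit on the same template within `max_len` yields
#' an amplicon whose length is the inclusive span from the leftmost to the
#' rightmost primer base. The band pattern is the set of product lengths
#' across all templates (both haplotypes of an individual).
#'
#' @param templates named character vector of template sequences.
#' @param primers list of [primer()] objects.
#' @param max_len maximum product length in bp.
#' @param max_mismatch per-primer mismatch allowance.
#' @return sorted integer vector of distinct amplicon lengths (bp).
#' @export
predict_amplicons <- function(templates, primers, max_len = 2000L,
                              max_mismatch = 1L) {
  bands <- integer(0)
  for (tmpl in templates) {
    fwd <- list(); rev <- list()
    for (pr in primers) {
      s <- find_primer_sites(tmpl, pr, max_mismatch)
      s$len <- rep(nchar(pr$sequence), nrow(s))
      fwd[[length(fwd) + 1L]] <- s[s$strand == "+", , drop = FALSE]
      rev[[length(rev) + 1L]] <- s[s$strand == "-", , drop = FALSE]
    }
    fwd <- do.call(rbind, fwd)
    rev <- do.call(rbind, rev)
    if (nrow(fwd) == 0 || nrow(rev) == 0) next
    for (i in seq_len(nrow(fwd))) {
      span <- rev$position + rev$len - fwd$position[i]
      ok <- rev$position > fwd$position[i] & span <= max_len
      bands <- c(bands, span[ok])
    }
  }
  sort(unique(as.integer(bands)))
}

#' Call a genotype from a band pattern
#'
#' Junction band only: homozygous transgenic (tg/tg); junction and
#' wild-type bands: heterozygous (tg/wt); wild-type band only: wt/wt;
#' anything else indeterminate.
#'
#' @param pattern integer vector of observed band lengths (bp).
#' @param junction_len expected junction (transgene) band length.
#' @param wildtype_len expected intact-locus band length.
#' @param tolerance band-length matching tolerance in bp.
#' @return one of `"tg/tg"`, `"tg/wt"`, `"wt/wt"`, `"indeterminate"`.
#' @export
call_genotype <- function(pattern, junction_len, wildtype_len,
                          tolerance = 3L) {
  if (abs(junction_len - wildtype_len) <= tolerance)
    stop("junction and wild-type bands are not distinguishable at this ",
         "tolerance")
  is_j <- abs(pattern - junction_len) <= tolerance
  is_w <- abs(pattern - wildtype_len) <= tolerance
  if (any(!(is_j | is_w))) return("indeterminate")
  has_j <- any(is_j); has_w <- any(is_w)
  if (has_j && has_w) "tg/wt"
  else if (has_j) "tg/tg"
  else if (has_w) "wt/wt"
  else "indeterminate"
}

#' Design junction-spanning genotyping primers for a simulated study
#'
#' Mirrors the published assay design: the transgene forward primer spans
#' the exit junction (its 5' portion annealing to the truncated 3' end of
#' the last concatemer copy, its final `host_anchor` bases to the host
#' sequence at the insertion), so it can only prime on the insertion
#' allele; the host primer pair flanks the insertion site and only yields a
#' product from the intact locus. Primer placement is chosen so the
#' junction and wild-type products have the requested lengths.
#'
#' @param fix a [make_fixture()] result (or any list with host, tg, truth).
#' @param junction_band,wildtype_band desired product lengths in bp.
#' @param tg_anchor,host_anchor junction primer arm lengths in nt.
#' @param host_primer_len lengths of the host forward/reverse primers.
#' @return list of three [primer()]s: junction_f, host_f, host_r.
#' @export
design_genotyping_primers <- function(fix, junction_band = 194L,
                                      wildtype_band = 202L,
                                      tg_anchor = 14L, host_anchor = 4L,
                                      host_primer_len = c(21L, 19L)) {
  tr <- fix$truth
  host <- fix$host
  tgs <- fix$tg$sequence
  junction_f <- primer(
    "junction_F",
    paste0(substr(tgs, tr$exit_tg - tg_anchor + 1L, tr$exit_tg),
           substr(host, tr$exit_host, tr$exit_host + host_anchor - 1L)),
    "forward")
  # host reverse primer ends where the junction product must end
  r_end <- tr$exit_host + junction_band - tg_anchor - 1L
  r_start <- r_end - host_primer_len[2] + 1L
  host_r <- primer("host_R", revcomp(substr(host, r_start, r_end)),
                   "reverse")
  # host forward primer starts where the wild-type product must start
  f_start <- r_end - wildtype_band + 1L
  host_f <- primer(
    "host_F", substr(host, f_start, f_start + host_primer_len[1] - 1L),
    "forward")
  list(junction_f = junction_f, host_f = host_f, host_r = host_r)
}

#' Genotype one individual by in-silico PCR
#'
#' @param haplotypes named character vector of the individual's two
#'   haplotype sequences.
#' @param primers list of [primer()]s (multiplexed in one reaction).
#' @param junction_len,wildtype_len,tolerance see [call_genotype()].
#' @param max_len maximum product length in bp.
#' @return list: genotype, bands.
#' @export
genotype_individual <- function(haplotypes, primers, junction_len = 194L,
                                wildtype_len = 202L, tolerance = 3L,
                                max_len = 2000L) {
  bands <- predict_amplicons(haplotypes, primers, max_len)
  list(genotype = call_genotype(bands, junction_len, wildtype_len,
                                tolerance),
       bands = bands)
}

#' Segregation statistics for an intercross
#'
#' Per-stage genotype percentages, the transgene-carrier percentage, the
#' carrier percentage expected under the supplied Mendelian ratio, and (as
#' added convenience; the assay itself reports only counts) a chi-square
#' goodness-of-fit statistic per stage against that ratio.
#'
#' @param counts data.frame with columns stage, wt, het, hom (counts per
#'   genotype class).
#' @param expected_ratio Mendelian class ratio (wt : het : hom).
#' @return list: per_stage (data.frame with percentages, totals, chisq and
#'   p), carrier_percent (pooled), expected_carrier_percent, total.
#' @export
cross_statistics <- function(counts, expected_ratio = c(1, 2, 1)) {
  counts$total <- counts$wt + counts$het + counts$hom
  if (sum(counts$total) == 0) stop("no individuals counted")
  p_exp <- expected_ratio / sum(expected_ratio)
  per_stage <- counts
  per_stage$wt_pct <- 100 * counts$wt / counts$total
  per_stage$het_pct <- 100 * counts$het / counts$total
  per_stage$hom_pct <- 100 * counts$hom / counts$total
  per_stage$carrier_pct <- 100 * (counts$het + counts$hom) / counts$total
  chi <- t(vapply(seq_len(nrow(counts)), function(i) {
    obs <- as.numeric(counts[i, c("wt", "het", "hom")])
    if (sum(obs) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(chisq.test(obs, p = p_exp))
    c(unname(ct$statistic), unname(ct$p.value))
  }, numeric(2)))
  per_stage$chisq <- chi[, 1]
  per_stage$p <- chi[, 2]
  list(per_stage = per_stage,
       carrier_percent = 100 * sum(counts$het + counts$hom) /
         sum(counts$total),
       expected_carrier_percent = 100 * (p_exp[2] + p_exp[3]),
       total = sum(counts$total))
}

#' Percentage of transgene carriers
#'
#' @param n_carriers,n_total carrier and total progeny counts.
#' @return percentage.
#' @export
carrier_percent <- function(n_carriers, n_total) {
  if (n_total == 0) stop("n_total must be positive")
  100 * n_carriers / n_total
}

#' Simulate a heterozygote intercross with genotype-specific viability
#'
#' Progeny genotypes are drawn from the Mendelian 1:2:1 distribution; each
#' survives with its genotype's viability (e.g. homozygote viability 0
#' models embryonic lethality of the disrupted locus).
#'
#' @param n_progeny number of conceptuses.
#' @param viability length-3 survival probabilities (wt, het, hom).
#' @param stage stage label for the output row.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return one-row data.frame: stage, wt, het, hom.
#' @export
simulate_cross <- function(n_progeny, viability = c(1, 1, 1),
                           stage = "cross", seed = NULL) {
  stopifnot(length(viability) == 3, all(viability >= 0),
            all(viability <= 1))
  if (!is.null(seed)) set.seed(seed)
  if (n_progeny == 0)
    return(data.frame(stage = stage, wt = 0L, het = 0L, hom = 0L,
                      stringsAsFactors = FALSE))
  g <- sample.int(3L, n_progeny, replace = TRUE,
                  prob = c(0.25, 0.5, 0.25))
  survived <- runif(n_progeny) < viability[g]
  tab <- tabulate(g[survived], nbins = 3L)
  data.frame(stage = stage, wt = tab[1], het = tab[2], hom = tab[3],
             stringsAsFactors = FALSE)
}
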