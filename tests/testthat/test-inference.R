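test_that("fusions classify into self / entry / exit / unrelated", {
  trio <- paper_fusion_trio()
  cls <- classify_fusions(trio, "WAP-Her2")
  expect_equal(nrow(cls$self_fusions), 1)
  expect_equal(nrow(cls$entry_fusions), 1)
  expect_equal(nrow(cls$exit_fusions), 1)
  expect_equal(nrow(cls$unrelated), 0)
  expect_equal(cls$self_fusions$pos_a, 6850)
  expect_equal(cls$entry_fusions$pos_b, 4025)
  expect_equal(cls$exit_fusions$pos_a, 2972)

  hosty <- trio[2, ]
  hosty$ref_b <- "chr11"
  expect_equal(nrow(classify_fusions(hosty, "WAP-Her2")$unrelated), 1)
  empty <- classify_fusions(trio[0, ], "WAP-Her2")
  expect_true(all(vapply(empty, nrow, 1L) == 0))
})

test_that("reconstruction reproduces the published junction arithmetic", {
  cls <- classify_fusions(paper_fusion_trio(), "WAP-Her2")
  al <- reconstruct_insertion(cls$entry_fusions, cls$exit_fusions,
                              cls$self_fusions)
  expect_equal(al$entry_host, 150719804)
  expect_equal(al$exit_host, 150719794)
  expect_equal(al$tsd_len, 10)
  expect_equal(al$entry_tg, 4025)
  expect_equal(al$exit_tg, 2972)
  expect_equal(al$unit_end_tg, 6850)
  expect_equal(al$orientation, "forward")

  # blunt insertion: equal entry and exit coordinates
  blunt <- cls
  blunt$exit_fusions$pos_b <- 150719804L
  ab <- reconstruct_insertion(blunt$entry_fusions, blunt$exit_fusions)
  expect_equal(ab$tsd_len, 0)

  # negative difference flags a deletion at the insertion site
  del <- cls
  del$exit_fusions$pos_b <- 150719900L
  ad <- reconstruct_insertion(del$entry_fusions, del$exit_fusions)
  expect_equal(ad$tsd_len, 0)
  expect_true("deletion_at_insertion_site" %in% ad$flags)

  # entry and exit on different host contigs: multi-site warning, no allele
  multi <- cls
  multi$exit_fusions$ref_b <- "chr11"
  expect_warning(am <- reconstruct_insertion(multi$entry_fusions,
                                             multi$exit_fusions),
                 "multi-site")
  expect_null(am)
})

test_that("depth profile tiles contigs and conserves aligned bases", {
  lens <- c(chr = 2500L)
  empty <- depth_profile(align_batch(character(0),
                                     index_reference(c(chr = random_dna(
                                       2500, seed = 91)), 20)),
                         lens, window = 500)
  expect_equal(nrow(empty), 5)
  expect_true(all(empty$depth == 0))
  expect_error(depth_profile(NULL, lens, window = 0), "window")

  ref <- random_dna(20000, seed = 92)
  idx <- index_reference(c(chr = ref), 20)
  rd <- simulate_reads(c(chr = ref), 10, err_rate = 0, seed = 93)
  mp <- map_pairs(rd, idx)
  prof <- depth_profile(mp$alignments, idx$lengths, window = 500)
  expect_lt(abs(median(prof$depth) - 10) / 10, 0.1)
  # conservation against a direct tally of aligned M bases
  expect_equal(sum(prof$depth * (prof$end - prof$start + 1)),
               sum(mp$alignments$m_len[!is.na(mp$alignments$pos)]))
})

test_that("copy-number estimation: identity, geometry inversion, zygosity", {
  # single-copy identity: transgene depth equal to per-haplotype depth
  prof1 <- data.frame(
    ref_name = rep(c("host1", "tg"), each = 10),
    start = rep(seq(1, 4501, by = 500), 2),
    end = rep(seq(500, 5000, by = 500), 2),
    depth = c(rep(24, 10), rep(12, 10)), stringsAsFactors = FALSE)
  est1 <- estimate_copy_number(prof1, "tg", "het")
  expect_equal(est1$copies_depth, 1.0)

  # geometry-aware inversion is exact on noise-free depth, het and hom
  geom <- list(entry_tg = 4025L, exit_tg = 2972L, unit_end_tg = 6850L)
  N <- 12; h <- 12
  total <- (geom$unit_end_tg - geom$entry_tg + 1) + (N - 2) *
    geom$unit_end_tg + geom$exit_tg
  tg_windows <- data.frame(ref_name = "tg", start = 1, end = 6884,
                           depth = h * total / 6884)
  host_windows <- data.frame(ref_name = "host1",
                             start = seq(1, 99501, 500),
                             end = seq(500, 1e5, 500), depth = 2 * h)
  for (zyg in c("het", "hom")) {
    prof <- rbind(host_windows,
                  within(tg_windows,
                         depth <- depth * ifelse(zyg == "hom", 2, 1)))
    est <- estimate_copy_number(prof, "tg", zyg, geometry = geom)
    expect_equal(est$copies_depth, N, tolerance = 1e-9)
    expect_equal(est$method, "geometry_corrected")
  }

  zero <- within(prof1, depth <- 0)
  expect_error(estimate_copy_number(zero, "tg", "het"), "zero host depth")
})

test_that("junction copy estimator follows its exact ratio arithmetic", {
  expect_equal(junction_copy_estimate(0, 8, 8), 1.0)
  expect_equal(junction_copy_estimate(11 * 7, 7, 7), 12.0)
  expect_equal(junction_copy_estimate(22, 10, 11, correction = TRUE),
               3.0)
  expect_warning(na <- junction_copy_estimate(50, 0, 5), "not available")
  expect_true(is.na(na))
})

test_that("total inserted length: published arithmetic, construction oracle,
           monotonicity", {
  geom <- list(entry_tg = 4025L, exit_tg = 2972L, unit_end_tg = 6850L)
  tl <- total_insert_length(geom, copies = 162, tg_length = 6884)
  expect_equal(tl$simple_nt, 1115208)          # 162 x 6884
  expect_equal(signif(tl$simple_nt / 1e6, 2), 1.1)  # reported as ~1.1 Mb

  full <- list(entry_tg = 1L, exit_tg = 6884L, unit_end_tg = 6884L)
  expect_equal(total_insert_length(full, copies = 1)$exact_nt, 6884)

  run <- toy_run()
  tr <- run$fix$truth
  measured <- nchar(run$fix$allele) - nchar(run$fix$host) -
    (tr$tsd_len + 1)
  expect_equal(total_insert_length(tr, tr$copies)$exact_nt, measured)

  lens <- vapply(2:6, function(n)
    total_insert_length(geom, copies = n)$exact_nt, 1)
  expect_true(all(diff(lens) > 0))
})

test_that("annotation distance matches the published 19 nt and a brute-force
           nearest-interval scan", {
  ann <- read_bed(extdata("exon3_annotation_synthetic.bed"))
  al <- list(host_contig = "chr5", entry_host = 150719804L)
  res <- annotate_position(al, ann)
  expect_equal(res$distance, 19)
  expect_equal(res$relation, "upstream")
  expect_equal(res$feature, "Pds5b_exon3")

  inside <- annotate_position(list(host_contig = "chr5",
                                   entry_host = 150719850L), ann)
  expect_equal(inside$distance, 0)
  expect_equal(inside$relation, "inside")

  none <- annotate_position(list(host_contig = "chrX",
                                 entry_host = 5L), ann)
  expect_true(is.na(none$feature))

  # brute-force oracle over a random annotation
  set.seed(95)
  starts <- sort(sample(1e5, 20))
  rand_ann <- data.frame(chrom = "c", start = starts,
                         end = starts + sample(50:500, 20, TRUE),
                         name = paste0("f", 1:20), strand = "+",
                         stringsAsFactors = FALSE)
  for (p in sample(1e5, 25)) {
    got <- annotate_position(list(host_contig = "c", entry_host = p),
                             rand_ann)
    brute <- min(vapply(seq_len(20), function(i) {
      if (p >= rand_ann$start[i] && p <= rand_ann$end[i]) 0L
      else min(abs(rand_ann$start[i] - p), abs(rand_ann$end[i] - p))
    }, 1L))
    expect_equal(got$distance, brute)
  }
})

test_that("orientation is uniform across junctions of a forward concatemer", {
  run <- toy_run()
  tgf <- run$fusions[run$fusions$ref_a == "transgene" |
                       run$fusions$ref_b == "transgene", ]
  expect_true(all(tgf$orient_a == "+" & tgf$orient_b == "+"))
})
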