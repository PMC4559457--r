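test_that("alignments without soft clips yield no clusters", {
  ref <- random_dna(3000, seed = 81)
  idx <- index_reference(c(chr = ref), k = 20)
  rd <- simulate_reads(c(chr = ref), 5, err_rate = 0, seed = 82)
  mp <- map_pairs(rd, idx)  # reads from the reference itself: no junctions
  expect_equal(nrow(collect_clusters(mp$alignments)), 0)
  expect_equal(nrow(collect_clusters(mp$alignments[0, ])), 0)
})

test_that("clusters form at both host junction flanks on the toy study", {
  run <- toy_run()
  cl <- collect_clusters(run$mp$alignments, min_support = 1)
  host_cl <- cl[cl$ref_name == "host1", ]
  # two clusters flank the integration site: entry (right side) and exit
  # (left side), at the truth coordinates
  expect_true(any(host_cl$side == "right" &
                    abs(host_cl$position - run$fix$truth$entry_host) <= 3))
  expect_true(any(host_cl$side == "left" &
                    abs(host_cl$position - run$fix$truth$exit_host) <= 3))
})

test_that("the min_support threshold drops clusters at the boundary", {
  ref <- random_dna(500, seed = 83)
  clip <- random_dna(30, seed = 84)
  aln <- do.call(rbind, lapply(1:10, function(i) data.frame(
    qname = paste0("r", i), mate = 1L, rname = "chr", pos = 101L,
    strand = "+", clip_left = 30L, m_len = 70L, clip_right = 0L,
    score = 140L, nm = 0L, seq = paste0(clip, substr(ref, 101, 170)),
    qual = strrep("I", 100), stringsAsFactors = FALSE)))
  expect_equal(nrow(collect_clusters(aln, min_support = 11)), 0)
  kept <- collect_clusters(aln, min_support = 10)
  expect_equal(kept$support, 10)
  expect_equal(kept$position, 101)
  expect_equal(kept$side, "left")
  expect_identical(kept$consensus_clip, clip)
})

test_that("a clip that realigns nowhere is reported unresolved", {
  ref <- c(chr = random_dna(2000, seed = 85))
  cl <- data.frame(ref_name = "chr", position = 500L, side = "right",
                   support = 5L,
                   consensus_clip = random_dna(40, seed = 86),
                   stringsAsFactors = FALSE)
  res <- realign_clips(cl, ref)
  expect_equal(nrow(res$fusions), 0)
  expect_equal(nrow(res$unresolved), 1)
})

test_that("planted microhomology is reported once, leftmost", {
  set.seed(87)
  refA <- random_dna(100)
  refB <- random_dna(200)
  mh <- "GGCC"
  # plant the homology so the junction A:100 -> B:51 can shift 4 nt left
  substr(refA, 97, 100) <- mh
  substr(refB, 47, 50) <- mh
  # forbid further accidental shifts at the window edges
  substr(refA, 96, 96) <- chartr("ACGT", "TGCA", substr(refB, 46, 46))
  substr(refB, 51, 51) <- chartr("ACGT", "TGCA", substr(refB, 51, 51))
  cl <- data.frame(ref_name = "A", position = 100L, side = "right",
                   support = 6L, consensus_clip = substr(refB, 51, 95),
                   stringsAsFactors = FALSE)
  res <- realign_clips(cl, c(A = refA, B = refB))
  f <- res$fusions
  expect_equal(nrow(f), 1)
  expect_identical(f$microhomology, mh)
  expect_equal(f$pos_a, 96)  # leftmost consistent junction position
  expect_equal(f$pos_b, 47)
})

test_that("fusion counts by copy number: 3 for a concatemer, 2 for a single
           copy, 0 without insertion", {
  run <- toy_run()
  tg_fus <- run$fusions[run$fusions$ref_a == "transgene" |
                          run$fusions$ref_b == "transgene", ]
  expect_equal(nrow(tg_fus), 3)

  run1 <- toy_run(copies = 1L, entry_tg = 100L, exit_tg = 1100L)
  tg1 <- run1$fusions[run1$fusions$ref_a == "transgene" |
                        run1$fusions$ref_b == "transgene", ]
  expect_equal(nrow(tg1), 2)  # entry and exit, no tandem junction

  cfg0 <- toy_config()
  fix0 <- make_fixture(cfg0, 1L)
  rd0 <- simulate_reads(c(hapA = fix0$host, hapB = fix0$host), 15,
                        err_rate = 0, seed = 88)
  idx0 <- index_reference(fix0$reference, 20)
  mp0 <- map_pairs(rd0, idx0)
  fus0 <- call_fusions(mp0$alignments, fix0$reference)
  expect_equal(nrow(fus0[fus0$ref_a == "transgene" |
                           fus0$ref_b == "transgene", ]), 0)
})

test_that("called fusion coordinates equal the simulated truth", {
  run <- toy_run()
  tr <- run$fix$truth
  f <- run$fusions
  entry <- f[f$ref_a == "host1" & f$ref_b == "transgene", ]
  exitf <- f[f$ref_a == "transgene" & f$ref_b == "host1", ]
  selff <- f[f$ref_a == "transgene" & f$ref_b == "transgene", ]
  expect_equal(entry$pos_a, tr$entry_host)
  expect_equal(entry$pos_b, tr$entry_tg)
  expect_equal(exitf$pos_a, tr$exit_tg)
  expect_equal(exitf$pos_b, tr$exit_host)
  expect_equal(selff$pos_a, tr$unit_end_tg)
  expect_equal(selff$pos_b, 1)
  # tandem junction support exceeds each host junction's support
  expect_gt(selff$support, entry$support)
  expect_gt(selff$support, exitf$support)
})

test_that("merging reciprocal fusion calls conserves total support", {
  fus <- data.frame(
    ref_a = c("h", "h", "t"), pos_a = c(500L, 500L, 90L),
    orient_a = "+",
    ref_b = c("t", "t", "h"), pos_b = c(40L, 41L, 800L),
    orient_b = "+",
    support = c(7L, 4L, 3L), microhomology = "", untemplated = "",
    stringsAsFactors = FALSE)
  merged <- concatmap:::merge_fusions(fus)
  expect_equal(nrow(merged), 2)
  expect_equal(sum(merged$support), sum(fus$support))
  expect_equal(merged$support[merged$ref_a == "h"], 11)
})
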