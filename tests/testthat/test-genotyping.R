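test_that("primer construction validates sequence and length", {
  expect_error(primer("p", "ACGTN" , "forward"), "A,C,G,T")
  expect_error(primer("p", "ACGTACGTAC", "forward"), "15-30")
  p <- primer("Pds5b_F", "GGACTATTTACAGGAAACGTC", "forward")
  expect_s3_class(p, "primer")
})

test_that("published primers load from the bundled table", {
  tab <- read.table(extdata("genotyping_primers.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  prs <- lapply(seq_len(nrow(tab)), function(i)
    primer(tab$name[i], tab$sequence[i], tab$role[i]))
  expect_equal(vapply(prs, function(p) nchar(p$sequence), 1L),
               c(21L, 19L, 18L))
})

test_that("primer site finding: planted sites, strands, 3' anchoring", {
  tmpl <- random_dna(2000, seed = 101)
  p <- primer("probe", random_dna(20, seed = 102), "forward")
  expect_equal(nrow(find_primer_sites(tmpl, p)), 0)

  planted <- paste0(substr(tmpl, 1, 700), p$sequence,
                    substr(tmpl, 701, 2000))
  hits <- find_primer_sites(planted, p)
  expect_equal(hits$position, 701)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  planted_rc <- paste0(substr(tmpl, 1, 700), revcomp(p$sequence),
                       substr(tmpl, 701, 2000))
  hits_rc <- find_primer_sites(planted_rc, p)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$position, 701)

  # one internal mismatch is tolerated; a 3'-terminal mismatch is not
  internal <- planted
  substr(internal, 705, 705) <- chartr("ACGT", "TGCA",
                                       substr(internal, 705, 705))
  expect_equal(nrow(find_primer_sites(internal, p)), 1)
  threep <- planted
  substr(threep, 720, 720) <- chartr("ACGT", "TGCA",
                                     substr(threep, 720, 720))
  expect_equal(nrow(find_primer_sites(threep, p)), 0)
})

test_that("the junction-spanning primer is specific to the insertion allele", {
  cfg <- toy_config(depth = 0)
  fix <- make_fixture(cfg, seed = 103)
  prs <- design_genotyping_primers(fix)
  expect_equal(nchar(prs$junction_f$sequence), 18)  # 14 nt transgene + 4 host
  expect_equal(nrow(find_primer_sites(fix$host, prs$junction_f)), 0)
  expect_equal(nrow(find_primer_sites(fix$tg$sequence, prs$junction_f)), 0)
  expect_gte(nrow(find_primer_sites(fix$allele, prs$junction_f)), 1)
})

test_that("band patterns genotype het, hom and wild-type individuals", {
  cfg <- toy_config(depth = 0)
  fix <- make_fixture(cfg, seed = 103)
  prs <- design_genotyping_primers(fix)

  expect_equal(predict_amplicons(c(x = random_dna(500, seed = 104)),
                                 prs), integer(0))

  het <- genotype_individual(c(a = fix$allele, b = fix$host), prs)
  hom <- genotype_individual(c(a = fix$allele, b = fix$allele), prs)
  wt <- genotype_individual(c(a = fix$host, b = fix$host), prs)
  expect_equal(het$bands, c(194L, 202L))
  expect_equal(het$genotype, "tg/wt")
  expect_equal(hom$bands, 194L)
  expect_equal(hom$genotype, "tg/tg")
  expect_equal(wt$bands, 202L)
  expect_equal(wt$genotype, "wt/wt")
})

test_that("genotype calls follow the published band logic", {
  expect_equal(call_genotype(194, 194, 202), "tg/tg")
  expect_equal(call_genotype(c(194, 202), 194, 202), "tg/wt")
  expect_equal(call_genotype(202, 194, 202), "wt/wt")
  expect_equal(call_genotype(integer(0), 194, 202), "indeterminate")
  expect_equal(call_genotype(c(194, 202, 350), 194, 202), "indeterminate")
  expect_equal(call_genotype(196, 194, 202, tolerance = 3), "tg/tg")
  expect_error(call_genotype(200, 200, 202), "not distinguishable")
})

test_that("segregation statistics reproduce the published percentages", {
  counts <- read.table(extdata("cross_counts.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  st <- cross_statistics(counts)
  e15 <- st$per_stage[st$per_stage$stage == "E15", ]
  expect_equal(e15$wt_pct, 17.5)
  expect_equal(e15$het_pct, 55)
  expect_equal(e15$hom_pct, 27.5)
  late <- st$per_stage[st$per_stage$stage == "E16_to_birth", ]
  expect_equal(late$hom_pct, 0)
  expect_equal(st$total, 79)
  expect_equal(st$expected_carrier_percent, 75)
  # per-stage percentages sum to 100
  expect_true(all(abs(st$per_stage$wt_pct + st$per_stage$het_pct +
                        st$per_stage$hom_pct - 100) < 1e-9))
  expect_true(all(is.finite(st$per_stage$chisq)))

  expect_equal(carrier_percent(239, 500), 47.8)
  expect_equal(round(carrier_percent(239, 500)), 48)
  expect_error(cross_statistics(data.frame(stage = "x", wt = 0, het = 0,
                                           hom = 0)), "no individuals")
})

test_that("simulated intercrosses follow Mendelian expectation and
           homozygote lethality", {
  expect_equal(sum(simulate_cross(0)[, c("wt", "het", "hom")]), 0)
  full <- simulate_cross(4000, seed = 105)
  n <- sum(full[, c("wt", "het", "hom")])
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(full$wt / n - 0.25), 3 * se)
  expect_lt(abs(full$het / n - 0.5), 3 * sqrt(0.5 * 0.5 / n))
  expect_lt(abs(full$hom / n - 0.25), 3 * se)

  # homozygote lethality: present early (viability 1), absent late
  early <- simulate_cross(2000, viability = c(1, 1, 1), stage = "E15",
                          seed = 106)
  late <- simulate_cross(2000, viability = c(1, 1, 0),
                         stage = "E16_to_birth", seed = 107)
  expect_gt(early$hom, 0)
  expect_equal(late$hom, 0)
  surv <- sum(late[, c("wt", "het", "hom")])
  carrier <- late$het / surv
  expect_lt(abs(carrier - 2 / 3), 3 * sqrt(2 / 9 / surv))

  expect_identical(simulate_cross(500, seed = 108),
                   simulate_cross(500, seed = 108))
})
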