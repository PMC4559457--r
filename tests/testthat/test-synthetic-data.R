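test_that("host genome generator honours length, alphabet, GC and seed", {
  expect_error(make_host_genome(0), "positive")
  expect_error(make_host_genome(100, gc_fraction = 1.5), "gc_fraction")

  s <- make_host_genome(10000, 0.5, seed = 7)
  expect_equal(nchar(s), 10000)
  expect_false(grepl("[^ACGT]", s))
  expect_identical(s, make_host_genome(10000, 0.5, seed = 7))

  # GC of a 1 Mb draw within 3 binomial standard errors of the target
  g <- make_host_genome(1e6, 0.42, seed = 1)
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / 1e6
  se <- sqrt(0.42 * 0.58 / 1e6)
  expect_lt(abs(gc - 0.42), 3 * se)
})

test_that("transgene model validates sequence and feature intervals", {
  expect_error(transgene_model("t", "ACGU"), "A,C,G,T,N")
  expect_error(
    transgene_model("t", "ACGT",
                    data.frame(label = "x", start = 1, end = 9)),
    "within")
  tg <- make_transgene_model(6884, seed = 2)
  expect_equal(tg$length, 6884)
  expect_equal(tg$features$label, c("promoter", "utr5", "orf", "utr3"))
  expect_true(all(tg$features$end <= 6884))
})

test_that("insertion allele equals an independent concatenation oracle", {
  host <- random_dna(1000, seed = 3)
  tg <- transgene_model("tg", random_dna(100, seed = 4))
  tr <- insertion_truth("h", 600, 595, copies = 3, entry_tg = 20,
                        exit_tg = 70, unit_end_tg = 90)
  allele <- build_insertion_allele(host, tr, tg)

  # naive oracle: explicit character-vector surgery, no substr arithmetic
  hc <- strsplit(host, "")[[1]]
  tc <- strsplit(tg$sequence, "")[[1]]
  oracle <- c(hc[1:600],
              tc[20:90], tc[1:90], tc[1:70],
              hc[595:1000])
  expect_identical(allele, paste(oracle, collapse = ""))
  expect_equal(nchar(allele), 1000 + tr$tsd_len + 1 + insert_span_nt(tr))
})

test_that("allele construction rejects invalid geometry", {
  host <- random_dna(500, seed = 5)
  tg <- transgene_model("tg", random_dna(50, seed = 6))
  expect_error(insertion_truth("h", 100, 90, copies = 0,
                               entry_tg = 1, exit_tg = 50,
                               unit_end_tg = 50), "copies")
  tr_bad <- insertion_truth("h", 600, 590, copies = 2, entry_tg = 1,
                            exit_tg = 50, unit_end_tg = 50)
  expect_error(build_insertion_allele(host, tr_bad, tg), "out of range")
  tr1 <- insertion_truth("h", 100, 100, copies = 1, entry_tg = 40,
                         exit_tg = 10, unit_end_tg = 50)
  expect_error(build_insertion_allele(host, tr1, tg), "entry_tg <= exit_tg")
})

test_that("allele length follows the closed form over random geometries", {
  set.seed(11)
  for (i in 1:12) {
    L_host <- sample(500:2000, 1)
    L_tg <- sample(60:300, 1)
    host <- random_dna(L_host)
    tg <- transgene_model("tg", random_dna(L_tg))
    exit_host <- sample(100:(L_host - 100), 1)
    tsd <- sample(0:12, 1)
    copies <- sample(1:6, 1)
    unit_end <- sample((L_tg - 20):L_tg, 1)
    if (copies == 1) {
      entry_tg <- sample(1:(L_tg / 2), 1)
      exit_tg <- sample((entry_tg + 1):L_tg, 1)
    } else {
      entry_tg <- sample(1:unit_end, 1)
      exit_tg <- sample(1:unit_end, 1)
    }
    tr <- insertion_truth("h", exit_host + tsd, exit_host, copies,
                          entry_tg, exit_tg, unit_end)
    allele <- build_insertion_allele(host, tr, tg)
    expect_equal(nchar(allele),
                 L_host + tsd + 1 + insert_span_nt(tr))
  }
})

test_that("the duplicated host span flanks both junctions verbatim", {
  set.seed(21)
  for (tsd in c(1, 4, 10)) {
    host <- random_dna(2000)
    tg <- transgene_model("tg", random_dna(150))
    tr <- insertion_truth("h", 1000 + tsd, 1000, copies = 2,
                          entry_tg = 30, exit_tg = 80, unit_end_tg = 140)
    allele <- build_insertion_allele(host, tr, tg)
    dup <- substr(host, tr$exit_host, tr$entry_host)  # tsd_len + 1 bases
    left_flank_end <- substr(allele, tr$entry_host - tsd, tr$entry_host)
    right_start <- tr$entry_host + insert_span_nt(tr) + 1
    right_flank_start <- substr(allele, right_start, right_start + tsd)
    expect_identical(left_flank_end, dup)
    expect_identical(right_flank_start, dup)
  }
})

test_that("read simulator meets its count, content and error contracts", {
  hap <- c(h1 = random_dna(1e6, seed = 31))
  expect_error(simulate_reads(hap, 10, read_len = 200, frag_mean = 150),
               "frag_mean")
  expect_equal(nrow(simulate_reads(hap, 0)), 0)

  rd <- simulate_reads(hap, 12, read_len = 100, err_rate = 0, seed = 32)
  expect_equal(nrow(rd), 60000, tolerance = 0.01)
  expect_true(all(nchar(rd$seq1) == 100, nchar(rd$seq2) == 100))
  expect_true(all(nchar(rd$qual1) == 100))

  # error-free reads are exact substrings of their source haplotype
  # (forward or reverse complement)
  idx <- sample(nrow(rd), 50)
  hit <- vapply(idx, function(i) {
    grepl(rd$seq1[i], hap, fixed = TRUE) ||
      grepl(revcomp(rd$seq1[i]), hap, fixed = TRUE)
  }, TRUE)
  expect_true(all(hit))

  # observed mismatch rate against the truth origin within 3 binomial SE
  e <- 0.005
  rde <- simulate_reads(c(h1 = substr(hap, 1, 2e5)), 10, err_rate = e,
                        seed = 33)
  frag <- substring(hap, rde$frag_start, rde$frag_start + rde$frag_len - 1)
  left <- substr(frag, 1, 100)
  truth1 <- ifelse(rde$strand == "+", left, revcomp(
    substr(frag, rde$frag_len - 99, rde$frag_len)))
  mm <- sum(vapply(seq_len(nrow(rde)), function(i)
    sum(strsplit(rde$seq1[i], "")[[1]] != strsplit(truth1[i], "")[[1]]),
    1L))
  n_bases <- 100 * nrow(rde)
  se <- sqrt(e * (1 - e) / n_bases)
  expect_lt(abs(mm / n_bases - e), 3 * se)
})

test_that("identical seeds reproduce byte-identical FASTA/FASTQ output", {
  d1 <- file.path(tempdir(), "fixA")
  d2 <- file.path(tempdir(), "fixB")
  cfg <- toy_config(depth = 2)
  write_fixture(make_fixture(cfg, seed = 9), d1)
  write_fixture(make_fixture(cfg, seed = 9), d2)
  for (f in c("haplotypes.fa", "reads_1.fq", "reads_2.fq", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
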