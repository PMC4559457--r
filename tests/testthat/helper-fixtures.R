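# Shared small-scale fixtures. The desk-scale "pds5b-like" study (200 kb
# host, 12 copies) is reserved for the acceptance tests; unit tests use a
# toy geometry that keeps every junction type but runs in seconds.

toy_config <- function(...) {
  default_config(
    host_length = 40000L, entry_host = 20010L, exit_host = 20000L,
    copies = 3L, tg_length = 1200L, entry_tg = 700L, exit_tg = 500L,
    unit_end_tg = 1150L, depth = 20, err_rate = 0, ...)
}

.toy_cache <- new.env(parent = emptyenv())

# simulate + map + call on a toy config, cached across tests
toy_run <- function(seed = 1L, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  cfg <- toy_config(...)
  fix <- make_fixture(cfg, seed)
  idx <- index_reference(fix$reference, cfg$k)
  mp <- map_pairs(fix$reads, idx)
  fusions <- call_fusions(mp$alignments, fix$reference, cfg$min_clip_len,
                          cfg$min_support, cfg$slop)
  out <- list(cfg = cfg, fix = fix, idx = idx, mp = mp, fusions = fusions)
  .toy_cache[[key]] <- out
  out
}

random_dna <- function(n, seed = NULL) make_host_genome(n, 0.5, seed)

extdata <- function(f) system.file("extdata", f, package = "concatmap")

# published in-scope coordinates used as worked-example inputs
paper_fusion_trio <- function() {
  data.frame(
    ref_a = c("WAP-Her2", "chr5", "WAP-Her2"),
    pos_a = c(6850L, 150719804L, 2972L),
    orient_a = "+",
    ref_b = c("WAP-Her2", "WAP-Her2", "chr5"),
    pos_b = c(1L, 4025L, 150719794L),
    orient_b = "+",
    support = c(100L, 10L, 10L),
    microhomology = "", untemplated = "",
    stringsAsFactors = FALSE)
}
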