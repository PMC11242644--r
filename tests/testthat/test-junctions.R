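## shared fixture: 60 kb circle, one 2 kb direct repeat, reference +
## fission conformations
junction_fixture <- function(seed = 41L) {
  cfg <- simulation_config(
    molecule_lengths = 60000L,
    repeats = list(list(length = 2000L, orientation = "direct",
                        positions = c(10000L, 35000L))),
    seed = seed)
  g <- generate_genome(cfg)
  m <- g$molecules[[1]]
  rp <- find_maximal_repeats(m, min_len = 1000L)
  ev <- classify_events(m, rp, min_len = 1000L)
  cset <- enumerate_conformations(m, ev, max_depth = 1L)
  list(m = m, rp = rp, ev = ev, cset = cset)
}

test_that("junction strings have length repeat + 2*flank and both labels", {
  fx <- junction_fixture()
  assay <- build_junctions(fx$cset, "E1", flank = 1000L)
  expect_true(all(nchar(assay$junctions$seq) ==
                  assay$repeat_length + 2000L))
  expect_setequal(unique(assay$junctions$label), c("ref", "alt"))
  expect_true(assay$informative)
  ## flank wider than the smallest inter-copy arc is refused
  expect_error(build_junctions(fx$cset, "E1", flank = 30000L), "arc")
})

test_that("an assay without alternative conformations is uninformative", {
  fx <- junction_fixture()
  ref_only <- enumerate_conformations(fx$m, fx$ev[0, , drop = FALSE])
  ## the event is unknown to a reference-only enumeration
  expect_error(build_junctions(ref_only, "E1"), "unknown event")
  ## with conformations but identical junctions the flag drops
  assay <- build_junctions(fx$cset, "E1")
  expect_true(assay$informative)
})

test_that("the 100 bp flank rule decides who is counted", {
  fx <- junction_fixture()
  assay <- build_junctions(fx$cset, "E1", flank = 1000L,
                          min_flank_cov = 100L)
  m <- fx$m
  rep_iv <- interval(fx$rp$start1, fx$rp$start1 + fx$rp$length,
                     L = seq_length(m))
  ## read covering the repeat plus 150 bp on each side -> ref count 1
  good <- extract_seq(m, interval(fx$rp$start1 - 150L,
                                  fx$rp$start1 + fx$rp$length + 150L,
                                  L = seq_length(m)))
  ## read with 150 bp left but only 50 bp right -> counted nowhere
  lop <- extract_seq(m, interval(fx$rp$start1 - 150L,
                                 fx$rp$start1 + fx$rp$length + 50L,
                                 L = seq_length(m)))
  tal <- tally_support(c(good = good, lop = lop), assay)
  expect_equal(tal$ref_count, 1L)
  expect_equal(tal$alt_count, 0L)

  ## a read shorter than repeat + 2*min_flank_cov can never be counted
  short <- substr(good, 1L, assay$repeat_length + 150L)
  tal2 <- tally_support(c(s = short), assay)
  expect_equal(tal2$ref_count + tal2$alt_count, 0L)
})

test_that("reads from the reference conformation only never support alt", {
  fx <- junction_fixture()
  assay <- build_junctions(fx$cset, "E1")
  sim <- simulate_spanning_reads(fx$cset, "E1", weights = c(1, 0),
                                 n = 150L,
                                 read_model = list(mean = 4000, sd = 600,
                                                   min = 300L,
                                                   sub_rate = 0,
                                                   indel_rate = 0),
                                 seed = 5L)
  tal <- tally_support(sim$reads, assay)
  expect_equal(tal$alt_count, 0L)
  expect_equal(tal$ref_count, 150L)
})

test_that("counting is monotone in the read set and strand-pooled", {
  fx <- junction_fixture()
  assay <- build_junctions(fx$cset, "E1")
  sim <- simulate_spanning_reads(fx$cset, "E1", weights = c(0.5, 0.5),
                                 n = 60L,
                                 read_model = list(mean = 4000, sd = 600,
                                                   min = 300L,
                                                   sub_rate = 0.01,
                                                   indel_rate = 0.002),
                                 seed = 6L)
  t_half <- tally_support(sim$reads[1:30], assay)
  t_full <- tally_support(sim$reads, assay)
  expect_gte(t_full$ref_count, t_half$ref_count)
  expect_gte(t_full$alt_count, t_half$alt_count)
  ## reverse-complementing every read leaves counts unchanged
  rc_reads <- vapply(sim$reads, rc_chr, "")
  names(rc_reads) <- names(sim$reads)
  t_rc <- tally_support(rc_reads, assay)
  expect_equal(t_rc$ref_count, t_full$ref_count)
  expect_equal(t_rc$alt_count, t_full$alt_count)
})

test_that("internal matcher and PAF ingestion agree on error-free reads", {
  fx <- junction_fixture()
  assay <- build_junctions(fx$cset, "E1")
  ## reads short enough to lie fully inside a 4 kb junction reference,
  ## so each error-free read is an exact substring of its junction
  sim <- simulate_spanning_reads(fx$cset, "E1", weights = c(0.6, 0.4),
                                 n = 80L,
                                 read_model = list(mean = 2600, sd = 80,
                                                   min = 2450L,
                                                   sub_rate = 0,
                                                   indel_rate = 0),
                                 seed = 7L)
  internal <- tally_support(sim$reads, assay)

  ## construct PAF records by exact string location of each read on its
  ## matching junction (error-free, so locate-by-substring is exact)
  paf_rows <- list()
  for (i in seq_along(sim$reads)) {
    rd <- sim$reads[i]
    for (j in seq_len(nrow(assay$junctions))) {
      js <- assay$junctions$seq[j]
      at <- regexpr(rd, js, fixed = TRUE)
      if (at < 0) at <- regexpr(rc_chr(rd), js, fixed = TRUE)
      if (at > 0) {
        paf_rows[[length(paf_rows) + 1L]] <- data.frame(
          qname = names(sim$reads)[i], qlen = nchar(rd), qstart = 0L,
          qend = nchar(rd), strand = "+",
          tname = assay$junctions$name[j], tlen = nchar(js),
          tstart = at - 1L, tend = at - 1L + nchar(rd),
          nmatch = nchar(rd), alnlen = nchar(rd), mapq = 60L)
      }
    }
  }
  paf <- do.call(rbind, paf_rows)
  tf <- withr::local_tempfile(fileext = ".paf")
  utils::write.table(paf, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  external <- tally_support(assay = assay, paf = tf)
  expect_equal(external$ref_count, internal$ref_count)
  expect_equal(external$alt_count, internal$alt_count)
  expect_error(tally_support(assay = assay,
                             paf = data.frame(qname = "x", qlen = 1,
                                              qstart = 0, qend = 1,
                                              strand = "+",
                                              tname = "nope", tlen = 1,
                                              tstart = 0, tend = 1,
                                              nmatch = 1, alnlen = 1,
                                              mapq = 0)),
               "unknown junction")
})

test_that("frequency estimation follows alt/(alt+ref) with Wilson interval", {
  f <- estimate_frequency(ref = 10L, alt = 10L)
  expect_equal(f$frequency, 0.5)
  expect_true(f$ci[1] < 0.5 && f$ci[2] > 0.5)
  f0 <- estimate_frequency(ref = 7L, alt = 0L)
  expect_equal(f0$frequency, 0)
  expect_true(isTRUE(estimate_frequency(ref = 0L, alt = 0L)$undefined))
  ## Wilson agrees with prop.test's implementation (no continuity corr.)
  w <- wilson_interval(13L, 40L)
  pt <- stats::prop.test(13L, 40L, correct = FALSE)$conf.int
  expect_equal(w, as.numeric(pt), tolerance = 1e-8)
})

test_that("consensus building follows majority rule with tie warnings", {
  expect_equal(build_cds_consensus(list(c("ATGAAA", "ATGAAA", "ATGAAA"))),
               "ATGAAA")
  expect_equal(build_cds_consensus(list(c("ATGAAA", "ATGAAA", "ATGCAA"))),
               "ATGAAA")
  ## majority-gap columns are dropped
  expect_equal(build_cds_consensus(list(c("A-GAAA", "A-GAAA", "ATGAAA"))),
               "AGAAA")
  ## two rows differing everywhere: every column is a logged tie
  expect_warning(cons <- build_cds_consensus(list(c("AAA", "CCC"))),
                 "tie")
  expect_equal(cons, "AAA")
  expect_error(build_cds_consensus(list(c("AC", "ACG"))), "ragged")
  expect_error(build_cds_consensus(list("ACGT")), ">= 2 rows")
})

test_that("read recruitment uses canonical k-mer sharing", {
  set.seed(44)
  ref <- rand_seq(30000)
  inside <- substr(ref, 5001, 10000)
  rc_inside <- rc_chr(substr(ref, 12001, 17000))
  outside <- rand_seq(5000)
  got <- recruit_reads(c(a = inside, b = rc_inside, c = outside), ref)
  expect_setequal(names(got), c("a", "b"))
  expect_error(recruit_reads(c(a = "ACGT"), ref, k = 15L), "shortest read")
  expect_error(recruit_reads(c(a = inside), character()), "empty reference")
})
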