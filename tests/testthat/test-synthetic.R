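test_that("a fixed seed fixes every emitted byte", {
  cfg <- simulation_config(molecule_lengths = c(30000L, 12000L),
                           repeats = list(list(length = 2000L,
                                               orientation = "direct")),
                           seed = 42L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(g1$molecules, f1)
  write_fasta(g2$molecules, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$truth, g2$truth)

  r1 <- simulate_reads(list(g1$molecules), 1,
                       list(n = 20L, mean = 3000, sd = 500, min = 200L,
                            sub_rate = 0.01, indel_rate = 0.002),
                       seed = 9L)
  r2 <- simulate_reads(list(g2$molecules), 1,
                       list(n = 20L, mean = 3000, sd = 500, min = 200L,
                            sub_rate = 0.01, indel_rate = 0.002),
                       seed = 9L)
  expect_identical(r1$reads, r2$reads)
})

test_that("background GC matches the target within binomial error", {
  cfg <- simulation_config(molecule_lengths = 200000L, gc = 0.452,
                           seed = 5L)
  g <- generate_genome(cfg)
  ## binomial se at n = 200,000 is ~0.0011; 0.005 is > 4 sigma
  expect_lt(abs(gc_content(g$molecules[[1]]) - 0.452), 0.005)
})

test_that("planted direct copies are recovered as one long maximal pair", {
  cfg <- simulation_config(molecule_lengths = 60000L,
                           repeats = list(list(length = 5000L,
                                               orientation = "direct")),
                           seed = 8L)
  g <- generate_genome(cfg)
  rp <- find_maximal_repeats(g$molecules[[1]], min_len = 4000L)
  expect_equal(nrow(rp), 1L)
  expect_gte(rp$length, 5000L)
  expect_equal(rp$orientation, "direct")
})

test_that("plastid insertion conserves length and honors divergence", {
  cfg <- simulation_config(molecule_lengths = c(60000L, 30000L), seed = 2L)
  g <- generate_genome(cfg)
  plastome <- withr::with_seed(3L, circseq("cp", rand_seq(20000)))
  len0 <- sum(vapply(g$molecules, seq_length, 0L))

  ins0 <- insert_plastid_fragments(g$molecules, plastome,
                                   spec = list(lengths = c(500L, 300L),
                                               divergence = 0),
                                   truth = g$truth, seed = 4L)
  expect_true(all(ins0$truth$mtpt$identity == 100))
  expect_equal(sum(vapply(ins0$molecules, seq_length, 0L)), len0 + 800L)

  ins2 <- insert_plastid_fragments(g$molecules, plastome,
                                   spec = list(lengths = rep(500L, 6L),
                                               divergence = 0.02),
                                   truth = g$truth, seed = 4L)
  ## binomial sd of realized identity at n=500, p=0.02 is ~0.63 points
  expect_true(all(abs(ins2$truth$mtpt$identity - 98) < 3 * 0.63 + 0.5))

  expect_error(
    insert_plastid_fragments(g$molecules, plastome,
                             spec = list(lengths = 50000L, divergence = 0)),
    "50%")
})

test_that("insertion truth shifts planted repeat coordinates correctly", {
  cfg <- simulation_config(molecule_lengths = 60000L,
                           repeats = list(list(length = 3000L,
                                               orientation = "direct")),
                           seed = 12L)
  g <- generate_genome(cfg)
  plastome <- withr::with_seed(13L, circseq("cp", rand_seq(10000)))
  ins <- insert_plastid_fragments(g$molecules, plastome,
                                  spec = list(lengths = rep(400L, 5L),
                                              divergence = 0),
                                  truth = g$truth, seed = 14L)
  m <- ins$molecules[[1]]
  tr <- ins$truth$repeats
  unit1 <- substr(m$residues, tr$start1[1] + 1L, tr$start1[1] + tr$length[1])
  unit2 <- substr(m$residues, tr$start2[1] + 1L, tr$start2[1] + tr$length[1])
  expect_identical(unit1, unit2)
  ## mtpt truth intervals carry the planted fragments
  mt <- ins$truth$mtpt
  for (i in seq_len(nrow(mt))) {
    got <- substr(m$residues, mt$start[i] + 1L, mt$end[i])
    src <- extract_seq(plastome, interval(mt$src_start[i], mt$src_end[i],
                                          strand = mt$strand[i],
                                          L = seq_length(plastome)))
    expect_identical(got, src)  # divergence 0
  }
})

test_that("read simulation respects counts, labels and error-free identity", {
  cfg <- simulation_config(molecule_lengths = c(20000L, 8000L), seed = 6L)
  g <- generate_genome(cfg)
  sim <- simulate_reads(list(g$molecules), 1,
                        list(n = 100L, mean = 2000, sd = 400, min = 200L,
                             sub_rate = 0, indel_rate = 0),
                        seed = 7L)
  expect_length(sim$reads, 100L)
  expect_equal(nrow(sim$truth), 100L)
  ## label soundness: every error-free read re-locates at its label
  ids <- vapply(g$molecules, `[[`, "", "id")
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    mol <- g$molecules[[match(tr$molecule, ids)]]
    expected <- extract_seq(mol, interval(tr$start, tr$start + tr$length,
                                          strand = tr$strand,
                                          L = seq_length(mol)))
    expect_identical(unname(sim$reads[i]), expected)
  }
})

test_that("conformation mixture weights are respected within 3 sigma", {
  cfg <- simulation_config(molecule_lengths = 20000L, seed = 10L)
  g <- generate_genome(cfg)
  altm <- list(seq_rotate(g$molecules[[1]], 5000L))
  sim <- simulate_reads(list(g$molecules, altm), c(0.5, 0.5),
                        list(n = 1000L, mean = 1500, sd = 300, min = 200L,
                             sub_rate = 0, indel_rate = 0),
                        seed = 11L)
  nA <- sum(sim$truth$conformation == 1L)
  expect_lt(abs(nA - 500), 3 * sqrt(1000 * 0.25) + 1)
})

test_that("degenerate read-length models and bad weights are rejected", {
  cfg <- simulation_config(molecule_lengths = 5000L, seed = 1L)
  g <- generate_genome(cfg)
  expect_error(
    simulate_reads(list(g$molecules), 1,
                   list(n = 5L, mean = -100, sd = 0, min = 0L,
                        sub_rate = 0, indel_rate = 0), seed = 1L),
    "length < 1")
  expect_error(
    simulate_reads(list(g$molecules), c(0.6, 0.6),
                   list(n = 5L, mean = 100, sd = 0, min = 50L,
                        sub_rate = 0, indel_rate = 0), seed = 1L))
  expect_error(simulation_config(weights = c(0.5, 0.4)), "sum to 1")
})
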