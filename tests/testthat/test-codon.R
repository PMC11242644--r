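test_that("CDS extraction splices exons, strands and trans-spliced genes", {
  set.seed(61)
  ## build molecules by "reverse splicing" a known coding sequence
  cds_seq <- rand_cds(60L)                 # 180 nt, no stops
  chunks <- substring(cds_seq, c(1, 37, 73, 109, 145),
                      c(36, 72, 108, 144, 180))
  m1 <- rand_seq(3000); m2 <- rand_seq(2000)
  ## exons 1,4,5 on molecule A (exon 4 on minus strand), exons 2,3 on B
  substr(m1, 101, 136) <- chunks[1]
  substr(m2, 501, 536) <- chunks[2]
  substr(m2, 1001, 1036) <- chunks[3]
  substr(m1, 1001, 1036) <- rc_chr(chunks[4])
  substr(m1, 2001, 2036) <- chunks[5]
  feats <- data.frame(
    seqid = c("A", "B", "B", "A", "A"),
    type = "CDS",
    start = c(100L, 500L, 1000L, 1000L, 2000L),
    end = c(136L, 536L, 1036L, 1036L, 2036L),
    strand = c("+", "+", "+", "-", "+"),
    gene = "nad1like", exon = 1:5, pseudo = FALSE)
  mols <- list(circseq("A", m1), circseq("B", m2))
  cds <- extract_cds(mols, feats)
  expect_length(cds, 1L)
  expect_identical(cds$nad1like$seq, cds_seq)
  expect_false(grepl("\\*", substr(translate_cds(cds$nad1like$seq,
                                                 trim_stop = FALSE),
                                   1, 59)))
})

test_that("frame violations and pseudogenes are filtered as specified", {
  m <- circseq("A", paste0("ATG", strrep("AAA", 5), "TAAGGGGG"))
  feats <- data.frame(seqid = "A", type = "CDS",
                      start = c(0L, 0L), end = c(21L, 26L),
                      strand = "+", gene = c("good", "offframe"),
                      exon = 1L, pseudo = c(FALSE, FALSE))
  expect_warning(cds <- extract_cds(list(m), feats), "not divisible by 3")
  expect_setequal(names(cds), "good")
  feats$pseudo <- c(FALSE, TRUE)
  cds2 <- suppressWarnings(extract_cds(list(m), feats))
  expect_setequal(names(cds2), "good")
  cds3 <- suppressWarnings(extract_cds(list(m), feats,
                                       include_pseudo = TRUE))
  expect_true("offframe" %in% names(cds3))
})

test_that("RSCU follows the family-normalized definition", {
  cu <- codon_usage("TTTTTTTTTTTC")       # Phe: TTT x3, TTC x1
  expect_equal(cu$rscu[["TTT"]], 1.5)
  expect_equal(cu$rscu[["TTC"]], 0.5)
  ## stop codons form one family of size 3
  cu2 <- codon_usage("TGATGA")
  expect_equal(cu2$rscu[["TGA"]], 3.0)
  ## uniform usage within families gives RSCU 1 everywhere used
  allc <- paste(names(Biostrings::GENETIC_CODE), collapse = "")
  cu3 <- codon_usage(allc)
  expect_true(all(abs(cu3$rscu - 1) < 1e-12))
  expect_equal(cu3$total, 64L)
})

test_that("RSCU family means equal 1 for random usage (property)", {
  set.seed(62)
  for (i in 1:10) {
    cu <- codon_usage(rand_cds(sample(50:500, 1L)))
    fam <- split(names(cu$rscu), Biostrings::GENETIC_CODE[names(cu$rscu)])
    for (f in fam) {
      if (sum(cu$counts[f]) == 0L) next
      expect_equal(mean(cu$rscu[f]), 1, tolerance = 1e-12)
    }
  }
})

test_that("Nei-Gojobori counts match hand-derived single-codon cases", {
  r <- nei_gojobori("TTTGGGAAA", "TTCGGGAAA")
  ## sites: TTT 1/3, GGG 1, AAA 1/3 (same for both sequences)
  expect_equal(r$S, 5 / 3)
  expect_equal(r$N, 9 - 5 / 3)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 0.6)
  expect_equal(r$Ks, -3 / 4 * log(1 - 0.8))
  expect_equal(r$Ka, 0)

  r0 <- nei_gojobori("ATGAAA", "ATGAAA")
  expect_equal(r0$Sd + r0$Nd, 0)
  expect_equal(c(r0$Ka, r0$Ks), c(0, 0))
  expect_true(r0$undefined$ratio)
})

test_that("Nei-Gojobori is symmetric and respects degenerate sites", {
  set.seed(63)
  a <- rand_cds(40L); b <- rand_cds(40L)
  ra <- nei_gojobori(a, b); rb <- nei_gojobori(b, a)
  for (f in c("S", "N", "Sd", "Nd", "pS", "pN"))
    expect_identical(ra[[f]], rb[[f]])

  ## differences only at 4-fold third positions are purely synonymous
  x <- strrep("GGT", 30L)
  y <- strrep("GGC", 30L)
  r4 <- nei_gojobori(x, y)
  expect_equal(r4$Nd, 0)
  expect_equal(r4$Ka, 0)
  expect_equal(r4$Sd, 30)
})

test_that("saturated alignments flag undefined distances without crashing", {
  set.seed(64)
  a <- rand_cds(300L)
  b <- rand_cds(300L)
  r <- nei_gojobori(a, b)
  expect_true(is.finite(r$S) && is.finite(r$N))
  expect_true(is.na(r$Ka) || is.na(r$Ks) || is.finite(r$ratio) ||
              is.na(r$ratio))
})

test_that("gapped and stop codons are skipped and tallied", {
  r <- nei_gojobori("ATG---AAATGA", "ATGCCCAAATGA")
  expect_equal(r$codons_compared, 2L)   # ATG and AAA
  expect_equal(r$codons_skipped, 2L)    # the gap codon and the stop
  expect_equal(r$S + r$N, 6)
})

test_that("pathway averaging matches the enumeration oracle on known pairs", {
  for (pair in list(c("TTT", "GTA"), c("ATG", "TGG"), c("AAA", "AGG"),
                    c("TCA", "ACT"), c("CGG", "AGA"))) {
    got <- nei_gojobori(pair[1], pair[2])
    want <- oracle_ng(pair[1], pair[2])
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$S, want$S, tolerance = 1e-12)
  }
})

test_that("protein mass and isoelectric point follow their definitions", {
  p <- protein_properties("G")
  expect_equal(p$mw_kda * 1000, 57.0519 + 18.0153, tolerance = 1e-6)
  ## poly-glycine pI is the midpoint of the terminal pKa values
  for (n in c(1L, 5L, 40L)) {
    pg <- protein_properties(strrep("G", n))
    expect_equal(pg$pi, (8.6 + 3.6) / 2, tolerance = 0.01)
  }
  ## net charge at the reported pI is zero
  set.seed(65)
  prot <- paste(sample(names(mitorec:::AA_MASS), 200L, replace = TRUE),
                collapse = "")
  pp <- protein_properties(prot)
  pka <- mitorec:::PKA_DEFAULT
  cnt <- table(factor(strsplit(prot, "")[[1]],
                      levels = names(mitorec:::AA_MASS)))
  q <- 1 / (1 + 10^(pp$pi - pka["Nterm"])) +
    cnt[["H"]] / (1 + 10^(pp$pi - pka["H"])) +
    cnt[["K"]] / (1 + 10^(pp$pi - pka["K"])) +
    cnt[["R"]] / (1 + 10^(pp$pi - pka["R"])) -
    1 / (1 + 10^(pka["Cterm"] - pp$pi)) -
    cnt[["D"]] / (1 + 10^(pka["D"] - pp$pi)) -
    cnt[["E"]] / (1 + 10^(pka["E"] - pp$pi)) -
    cnt[["C"]] / (1 + 10^(pka["C"] - pp$pi)) -
    cnt[["Y"]] / (1 + 10^(pka["Y"] - pp$pi))
  expect_lt(abs(q), 1e-3)
  expect_error(protein_properties(""), "empty")
  expect_error(protein_properties("GXXG"), "non-standard")
})
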