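test_that("identity handles exact, simple and pre-aligned cases", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  # internal gaps count as mismatch columns, terminal overhangs do not
  expect_equal(pairwise_identity("AC-GT", "ACCGT"), 80)
  expect_equal(pairwise_identity("ACGT--", "ACGTAA"), 100)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("protein identity translates in-frame nucleotide input", {
  # TTT TTC both encode F: nucleotide identity < protein identity
  expect_equal(pairwise_identity("TTTGCT", "TTCGCT", level = "protein"),
               100)
  expect_lt(pairwise_identity("TTTGCT", "TTCGCT"), 100)
})

test_that("the aligner agrees with an affine-gap DP oracle", {
  set.seed(7)
  for (i in 1:6) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    bv <- strsplit(a, "")[[1]]
    hit <- sample(60, 8)
    bv[hit] <- sdrscan:::mutate_base(bv[hit])
    bv <- bv[-sample(60, 3)]          # a deletion-bearing homolog
    b <- paste(bv, collapse = "")
    aln <- sdrscan:::align_global(a, b, "nucleotide")
    orc <- oracle_nw(a, b)
    expect_equal(aln$score, orc$score)
    expect_equal(pairwise_identity(a, b), orc$identity)
  }
})

test_that("NG86 handles the forced single-difference cases", {
  r0 <- ng86_kaks("TTTGCT", "TTTGCT")
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$omega))
  expect_identical(r0$selection_class, "undefined")
  r1 <- ng86_kaks("TTT", "TTC")     # Phe -> Phe: synonymous
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  r2 <- ng86_kaks("TTT", "TGT")     # Phe -> Cys: nonsynonymous
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)
})

test_that("NG86 counts equal brute-force pathway enumeration", {
  set.seed(3)
  tab <- sdrscan:::ng86_tables()
  sense <- tab$codons[tab$aa != "*"]
  for (rep_i in 1:40) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    r <- ng86_kaks(c1, c2)
    orc <- oracle_codon_diffs(c1, c2)
    expect_equal(r$Sd, unname(orc["sd"]), tolerance = 1e-12)
    expect_equal(r$Nd, unname(orc["nd"]), tolerance = 1e-12)
    expect_equal(r$S_sites,
                 (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("NG86 is symmetric and conserves sites and differences", {
  set.seed(9)
  a <- random_codon_seq(100)
  bv <- strsplit(a, "")[[1]]
  hit <- sample(300, 30)
  bv[hit] <- sdrscan:::mutate_base(bv[hit])
  b <- paste(bv, collapse = "")
  if (grepl("TAA|TAG|TGA", b)) b <- a   # guard: keep in-frame stop-free
  exons <- c(30, 40, 30)
  r_ab <- ng86_kaks(a, b, exons = exons)
  r_ba <- ng86_kaks(b, a, exons = exons)
  expect_equal(r_ab[, -1], r_ba[, -1])
  gene <- r_ab[r_ab$region == "gene", ]
  ex <- r_ab[r_ab$region != "gene", ]
  # site conservation: N + S = 3 x codons, exactly
  expect_equal(gene$N_sites + gene$S_sites, 3 * gene$codons)
  expect_equal(ex$N_sites + ex$S_sites, 3 * ex$codons)
  # per-exon counts add up to the whole gene
  expect_equal(sum(ex$Nd), gene$Nd)
  expect_equal(sum(ex$Sd), gene$Sd)
  expect_equal(sum(ex$S_sites), gene$S_sites)
})

test_that("selection classification weighs omega against evidence", {
  big <- data.frame(N_sites = 750, S_sites = 250, Nd = 10, Sd = 120,
                    Ks = 0.6, omega = 0.02)
  expect_identical(classify_selection(big), "purifying")
  weak <- data.frame(N_sites = 75, S_sites = 25, Nd = 2, Sd = 0.5,
                     Ks = 0.02, omega = 3)
  expect_identical(classify_selection(weak), "neutral")
  zero <- data.frame(N_sites = 75, S_sites = 25, Nd = 5, Sd = 0,
                     Ks = 0, omega = NA_real_)
  expect_identical(classify_selection(zero), "undefined")
  strong <- data.frame(N_sites = 300, S_sites = 100, Nd = 90, Sd = 2,
                       Ks = 0.02, omega = 15)
  expect_identical(classify_selection(strong), "positive")
})

test_that("Ks dating is the molecular-clock arithmetic", {
  expect_equal(date_duplication(0, rate = 1e-9), 0)
  expect_equal(date_duplication(0.35, rate = 3.5e-9), 50)
  expect_equal(date_duplication(0.35, rate = 7e-9), 25)  # doubling halves
  expect_equal(date_duplication(c(0.308, 0.357), rate = 3.5e-9),
               c(44, 51))
  expect_error(date_duplication(0.35, rate = -1), "rate")
})

test_that("indels are frameshift iff length change is not 3n", {
  expect_identical(classify_indel("A", "AT"), "frameshift")   # +1 bp
  expect_identical(classify_indel("A", "ATTT"), "in_frame")   # +3 bp
  expect_identical(classify_indel("ACT", "A"), "frameshift")  # -2 bp
  expect_identical(classify_indel("ACTT", "A"), "in_frame")   # -3 bp
  expect_identical(classify_indel("C", "G"), "in_frame")      # substitution
  expect_error(classify_indel("", "A"), "non-empty")
})
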