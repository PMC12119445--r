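test_that("window tiling follows the width/step/truncation contract", {
  w <- make_windows(100000, 50000, 25000)
  expect_equal(w$start, c(0, 25000, 50000))
  expect_equal(w$end, c(50000, 75000, 100000))
  w1 <- make_windows(50000, 50000, 25000)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(0, 50000))
  w2 <- make_windows(60000, 50000, 25000)
  expect_equal(w2$start, c(0, 25000))
  expect_equal(w2$end, c(50000, 60000))
  expect_error(make_windows(1e5, 25000, 50000), "step")
  expect_error(make_windows(1e5, 0, 0), "step")
  expect_error(make_windows(1e4, 50000, 25000), "exceeds")
})

geno_from_counts <- function(m_het, m_hom, f_het, f_hom, n = 8) {
  # build one site's genotype row: given het/hom-alt counts per sex
  g <- c(rep(1L, m_het), rep(2L, m_hom), rep(0L, n - m_het - m_hom),
         rep(1L, f_het), rep(2L, f_hom), rep(0L, n - f_het - f_hom))
  matrix(g, nrow = 1)
}

sexes16 <- rep(c("M", "F"), each = 8)

test_that("balanced allele frequencies give p = 1 and Fst = 0", {
  a <- snp_sex_association(geno_from_counts(8, 0, 8, 0), sexes16)
  expect_equal(a$p_value, 1)
  expect_equal(a$fst, 0)
})

test_that("a fixed difference gives Fst 1 and the enumerated exact p", {
  g <- geno_from_counts(0, 8, 0, 0)       # males 16/16 ALT, females 0/16
  a <- snp_sex_association(g, sexes16)
  expect_equal(a$fst, 1)
  expect_equal(a$p_value, oracle_fisher_p(0, 16, 16, 0), tolerance = 1e-12)
})

test_that("sites missing a whole sex are skipped and tallied", {
  g <- rbind(c(rep(2L, 8), rep(NA_integer_, 8)),    # Y-specific style
             geno_from_counts(8, 0, 8, 0))
  a <- snp_sex_association(g, sexes16)
  expect_equal(nrow(a), 1)
  expect_equal(attr(a, "skipped"), 1)
})

test_that("monomorphic sites are flagged with p = 1, fst = 0", {
  a <- snp_sex_association(geno_from_counts(0, 0, 0, 0), sexes16)
  expect_true(a$monomorphic)
  expect_equal(a$p_value, 1)
  expect_equal(a$fst, 0)
})

test_that("windowed Fst is the ratio of summed Hudson components", {
  set.seed(42)
  n_sites <- 40
  geno <- matrix(rbinom(n_sites * 16, 2, runif(n_sites, 0.1, 0.9)),
                 n_sites, 16)
  geno[1:5, 1:8] <- 2L   # some strongly differentiated sites
  geno[1:5, 9:16] <- 0L
  sites <- data.frame(contig = "chrY",
                      pos = sort(sample(0:49999, n_sites)))
  a <- snp_sex_association(geno, sexes16, sites)
  win <- make_windows(50000, 25000, 12500)
  wf <- window_fst(a, win)
  for (i in seq_len(nrow(win))) {
    j <- a$pos >= win$start[i] & a$pos < win$end[i]
    if (!any(j)) {
      expect_true(is.na(wf[i]))
    } else {
      # brute-force recomputation from the raw per-site components
      expect_equal(as.numeric(wf[i]),
                   min(1, max(0, sum(a$fst_num[j]) / sum(a$fst_den[j]))))
    }
  }
  # SNP input order does not matter
  ord <- sample(n_sites)
  a2 <- snp_sex_association(geno[ord, ], sexes16, sites[ord, ])
  expect_equal(as.numeric(window_fst(a2, win)), as.numeric(wf))
})

test_that("window coverage averages bins and ignores cohort duplication", {
  bins <- data.frame(contig = "c", start = seq(0, 9e4, 1e4),
                     end = seq(1e4, 1e5, 1e4))
  depth <- matrix(30, 10, 4, dimnames = list(NULL, paste0("i", 1:4)))
  prof <- normalize_depth(depth_fixture(depth, bins,
                                        c("M", "M", "F", "F")))
  win <- make_windows(1e5, 2e4, 1e4)
  cov <- window_coverage(prof, win, "c")
  expect_true(all(cov$cov_male == 1))
  expect_true(all(cov$cov_female == 1))
  # duplicating every individual leaves the per-sex means unchanged
  depth8 <- cbind(depth, depth)
  colnames(depth8) <- paste0("i", 1:8)
  prof8 <- normalize_depth(depth_fixture(depth8, bins,
                                         rep(c("M", "M", "F", "F"), 2)))
  expect_equal(window_coverage(prof8, win, "c"), cov)
})

test_that("dxy matches hand values and the Jukes-Cantor closed form", {
  map1 <- data.frame(x_start = 0, x_end = 4, y_start = 0, y_end = 4)
  win1 <- data.frame(start = 0, end = 4)
  expect_equal(window_dxy("AAAA", "AAAA", map1, win1,
                          min_aligned_sites = 1)$dxy, 0)
  expect_equal(window_dxy("AAAT", "AAAA", map1, win1,
                          min_aligned_sites = 1)$dxy, 0.25)
  jc <- window_dxy("AAAT", "AAAA", map1, win1, jc = TRUE,
                   min_aligned_sites = 1)$dxy
  expect_equal(jc, -0.75 * log(1 - 4 * 0.25 / 3), tolerance = 1e-4)
  expect_equal(round(jc, 4), 0.3041)
})

test_that("dxy over a concatenation equals the weighted window mean", {
  set.seed(11)
  x <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  y_chars <- strsplit(x, "")[[1]]
  hit <- sample(6000, 300)
  y_chars[hit] <- sdrscan:::mutate_base(y_chars[hit])
  y <- paste(y_chars, collapse = "")
  map <- data.frame(x_start = 0, x_end = 6000, y_start = 0, y_end = 6000)
  tiles <- make_windows(6000, 2000, 2000)
  d <- window_dxy(x, y, map, tiles, min_aligned_sites = 1)
  whole <- window_dxy(x, y, map, data.frame(start = 0, end = 6000),
                      min_aligned_sites = 1)
  expect_equal(sum(d$dxy * d$aligned_sites) / sum(d$aligned_sites),
               whole$dxy)
})

test_that("SDR window qualification and merging follow the rules", {
  base <- data.frame(start = seq(0, 9e4, 1e4), end = seq(2e4, 11e4, 1e4),
                     n_snps = 5L, n_assoc = 0L, max_neg_log_p = 0.5,
                     mean_fst = 0, cov_male = 1, cov_female = 1,
                     dxy = 0, n_y_specific = 0L)
  # a window whose best SNP has -logP = 2.5 qualifies
  st <- base
  st$max_neg_log_p[4] <- 2.5
  st$n_assoc[4] <- 1L
  call <- call_sdr(st)
  expect_equal(nrow(call$intervals), 1)
  expect_true(call$window_flags$assoc[4])
  # all-null stats give an empty call
  empty <- call_sdr(base)
  expect_equal(nrow(empty$intervals), 0)
  expect_output(print(empty), "none found")
  # female absence with male half-depth qualifies
  st2 <- base
  st2$cov_female[6] <- 0.01
  st2$cov_male[6] <- 0.5
  expect_true(call_sdr(st2)$window_flags$coverage[6])
  # a one-window gap is bridged, a two-window gap is not
  st3 <- base
  st3$dxy[c(2, 4)] <- 0.1
  expect_equal(nrow(call_sdr(st3)$intervals), 1)
  st4 <- base
  st4$dxy[c(2, 5)] <- 0.1
  expect_equal(nrow(call_sdr(st4)$intervals), 2)
  # lone low-enrichment hits do not qualify (fraction rule)
  st5 <- base
  st5$n_snps <- 100L
  st5$max_neg_log_p[4] <- 2.5
  st5$n_assoc[4] <- 1L
  expect_equal(nrow(call_sdr(st5)$intervals), 0)
})

test_that("marker presence association flags perfect separation", {
  res <- marker_presence_association(rep(c(TRUE, FALSE), each = 8),
                                     rep(c("M", "F"), each = 8))
  expect_true(res$perfect_separation)
  expect_equal(res$p_value, oracle_fisher_p(8, 0, 0, 8), tolerance = 1e-12)
  # marker present in everyone: no association
  res2 <- marker_presence_association(rep(TRUE, 16),
                                      rep(c("M", "F"), each = 8))
  expect_equal(res2$p_value, 1)
  expect_false(res2$perfect_separation)
})

test_that("the simulated SDR is recovered on the scaled genome", {
  cfg <- run_config(sim = as.list(small_cfg(seed = 21))[
    c("n_autosomes", "autosome_length", "sex_chrom_length", "sdr_start",
      "sdr_end", "block_size", "bin_size", "sdg_flank")],
    window = 2e4, step = 1e4, seed = 21, stages = "scan")
  rep <- run_pipeline(cfg)
  expect_equal(nrow(rep$scan$sdr_call$intervals), 1)
  expect_gte(rep$scan$jaccard, 0.8)
  # simulated Y-specific windows: female near zero, male near half
  flags <- rep$scan$sdr_call$window_flags
  covw <- rep$scan$windows[flags$coverage, ]
  expect_true(all(covw$cov_female < 0.1))
  expect_true(all(abs(covw$cov_male - 0.5) < 0.2))
})
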