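test_that("repeat density is forced interval arithmetic", {
  win <- make_windows(50000, 50000, 50000)
  empty <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), class = character(0))
  d0 <- repeat_density(empty, win, "c", classes = "LINE")
  expect_equal(d0$LINE, 0)
  one <- data.frame(contig = "c", start = 0, end = 25000, class = "LINE")
  expect_equal(repeat_density(one, win, "c")$LINE, 0.5)
})

test_that("density is idempotent under pre-merging and order-free", {
  set.seed(5)
  track <- data.frame(contig = "c",
                      start = sample(0:90000, 60, replace = TRUE),
                      class = sample(c("LINE", "LTR"), 60, TRUE))
  track$end <- pmin(track$start + sample(500:5000, 60, TRUE), 1e5)
  win <- make_windows(1e5, 2e4, 1e4)
  d1 <- repeat_density(track, win, "c")
  # pre-merge same-class intervals: unchanged densities
  merged <- do.call(rbind, lapply(split(track, track$class), function(tr) {
    red <- IRanges::reduce(IRanges::IRanges(tr$start + 1, tr$end))
    data.frame(contig = "c", start = IRanges::start(red) - 1,
               end = IRanges::end(red), class = tr$class[1])
  }))
  expect_equal(repeat_density(merged, win, "c"), d1,
               ignore_attr = TRUE)
  # interval order does not matter
  expect_equal(repeat_density(track[sample(nrow(track)), ], win, "c"),
               d1, ignore_attr = TRUE)
})

test_that("masked bp is conserved under non-overlapping tiling", {
  set.seed(6)
  track <- data.frame(contig = "c",
                      start = sample(0:95000, 40, TRUE),
                      class = "LINE")
  track$end <- pmin(track$start + sample(100:4000, 40, TRUE), 1e5)
  tiles <- make_windows(1e5, 1e4, 1e4)     # step = width
  d <- repeat_density(track, tiles, "c")
  total <- sum(d$LINE * (d$end - d$start))
  merged <- IRanges::reduce(IRanges::IRanges(track$start + 1, track$end))
  expect_equal(total, sum(IRanges::width(merged)))
})

test_that("region enrichment reports folds and calibrated permutation p", {
  # A twice as dense as B: fold 2, arithmetic forced
  track <- data.frame(
    contig = "c",
    start = c(seq(0, 90000, 1e4), seq(100000, 190000, 2e4)),
    class = "LINE")
  track$end <- track$start + 1000
  a <- list(contig = "c", start = 0, end = 1e5)
  b <- list(contig = "c", start = 1e5, end = 2e5)
  res <- region_enrichment(track, a, b, "LINE", n_perm = 200)
  expect_equal(res$density_a, 0.10)
  expect_equal(res$density_b, 0.05)
  expect_equal(res$fold, 2)
  expect_true(res$fisher_caveat)
  # identical density pattern in both regions: permutation p near 1
  track2 <- data.frame(contig = "c",
                       start = c(seq(0, 99000, 5000),
                                 seq(100000, 199000, 5000)),
                       class = "LINE")
  track2$end <- track2$start + 1000
  res2 <- region_enrichment(track2, a, b, "LINE", n_perm = 200)
  expect_gt(res2$p_perm, 0.5)
  expect_error(region_enrichment(track, a, a, "LINE"), "disjoint")
  expect_error(region_enrichment(track, list(contig = "c", start = 1,
                                             end = 1), b, "LINE"),
               "zero-length")
})

test_that("simulated LINE enrichment near the SDG is detected", {
  # default-scale genomes: 100 kbp flanks give the permutation test its
  # intended block count
  hits <- vapply(1:5, function(s) {
    g <- simulate_genome(sim_config(seed = s))
    sdg <- g$genes[g$genes$gene_id == g$sdg, ]
    par <- g$genes[g$genes$gene_id == "amh_a", ]
    res <- region_enrichment(
      g$repeats,
      list(contig = "chrY", start = max(0, sdg$start - 1e5),
           end = min(2e6, sdg$end + 1e5)),
      list(contig = "chr1", start = max(0, par$start - 1e5),
           end = min(2e6, par$end + 1e5)),
      "LINE", n_perm = 500, seed = s)
    res$p_perm < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("RepeatMasker .out files parse to 0-based classed intervals", {
  out <- file.path(tempdir(), "rm.out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat class/family",
    "",
    "  463   1.3  0.6  1.7  chr1      101   600  (9400) + L1MA4  LINE/L1       1  500    (0)   1",
    "  240  24.4  3.4  0.0  chr1     1001  1500  (8500) C MLT1A  LTR/ERVL-MaLR 1  500    (0)   2"
  ), out)
  track <- read_repeatmasker_out(out)
  expect_equal(track$start, c(100, 1000))
  expect_equal(track$end, c(600, 1500))
  expect_equal(track$class, c("LINE", "LTR"))
})
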