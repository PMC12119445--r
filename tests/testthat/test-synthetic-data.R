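test_that("invalid simulation configurations fail naming the field", {
  expect_error(sim_config(sdr_start = -1), "sdr_start")
  expect_error(sim_config(sdr_start = 2e6, sdr_end = 1e6), "sdr_start")
  expect_error(sim_config(sdr_end = 3e6), "sdr_end")
  expect_error(sim_config(n_males = 0), "n_males")
  expect_error(sim_config(snp_density = 1.5), "snp_density")
  expect_error(sim_config(depth_dispersion = -0.1), "depth_dispersion")
})

test_that("genome carries the configured SDR and one X/Y pair", {
  g <- simulate_genome(sim_config(sdr_start = 5e5, sdr_end = 1.9e6,
                                  seed = 3))
  expect_equal(g$sdr_truth$start, 5e5)
  expect_equal(g$sdr_truth$end, 1.9e6)
  expect_equal(sum(g$contigs$true_class == "X_linked"), 1)
  expect_equal(sum(g$contigs$true_class == "Y_linked"), 1)
  # annotations stay within contig bounds (0-based half-open)
  lens <- setNames(g$contigs$length, g$contigs$contig)
  expect_true(all(g$genes$start >= 0 & g$genes$end <= lens[g$genes$contig]))
  expect_true(all(g$repeats$start >= 0 &
                    g$repeats$end <= lens[g$repeats$contig]))
  # the SDG duplicate sits inside the truth interval on the Y
  sdg <- g$genes[g$genes$gene_id == g$sdg, ]
  expect_identical(sdg$contig, "chrY")
  expect_gte(sdg$start, g$sdr_truth$start)
  expect_lte(sdg$end, g$sdr_truth$end)
})

test_that("simulation is deterministic given seed and config", {
  g1 <- simulate_genome(small_cfg(seed = 7))
  g2 <- simulate_genome(small_cfg(seed = 7))
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$repeats, g2$repeats)
  s1 <- simulate_samples(g1)
  s2 <- simulate_samples(g2)
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$depth, s2$depth)
  g3 <- simulate_genome(small_cfg(seed = 8))
  expect_false(identical(as.character(g1$sequences[["chrX"]]),
                         as.character(g3$sequences[["chrX"]])))
})

test_that("without LINE enrichment the SDG flank matches background", {
  dens <- sapply(1:8, function(s) {
    g <- simulate_genome(small_cfg(seed = s, line_enrichment_factor = 1))
    sdg <- g$genes[g$genes$gene_id == g$sdg, ]
    fl <- list(contig = "chrY", start = max(0, sdg$start - 2e4),
               end = min(2e5, sdg$end + 2e4))
    sel <- g$repeats$contig == "chrY" & g$repeats$class == "LINE"
    merged <- IRanges::reduce(IRanges::IRanges(g$repeats$start[sel] + 1,
                                               g$repeats$end[sel]))
    flank <- sum(IRanges::width(IRanges::restrict(merged, fl$start + 1,
                                                  fl$end))) /
      (fl$end - fl$start)
    genome_bg <- sum(IRanges::width(merged)) / 2e5
    c(flank, genome_bg)
  })
  # flank density matches genome background within sampling error
  expect_lt(abs(mean(dens[1, ]) - mean(dens[2, ])), 0.03)
})

test_that("noise-free depth equals its expectation exactly", {
  cfg <- small_cfg(depth_dispersion = 0)
  g <- simulate_genome(cfg)
  s <- simulate_samples(g, cfg)
  males <- s$individuals$sex == "M"
  ys <- g$sdr_blocks[g$sdr_blocks$type == "y_specific", ]
  on_ys <- s$depth_bins$contig == "chrY" &
    apply(outer(s$depth_bins$start, ys$start, ">=") &
            outer(s$depth_bins$end, ys$end, "<="), 1, any)
  expect_true(any(on_ys))
  expect_true(all(s$depth[on_ys, males] == cfg$mean_depth / 2))
  expect_true(all(s$depth[on_ys, !males] == 0))
  auto <- s$depth_bins$contig %in% paste0("chr", 1:4)
  expect_true(all(s$depth[auto, ] == cfg$mean_depth))
})

test_that("females carry no genotype at Y-specific sites", {
  s <- simulate_samples(simulate_genome(small_cfg(seed = 2)))
  females <- s$individuals$sex == "F"
  ysp <- s$sites$type == "y_specific"
  expect_gt(sum(ysp), 0)
  expect_true(all(is.na(s$geno[ysp, females])))
  # and every male genotype there is hemizygous (never heterozygous)
  expect_false(any(s$geno[ysp, !females] == 1L, na.rm = TRUE))
})

test_that("female depth vanishes over Y-specific SDR sequence", {
  cfg <- sim_config(seed = 4)   # 8M + 8F, 30x
  g <- simulate_genome(cfg)
  s <- simulate_samples(g, cfg)
  females <- s$individuals$sex == "F"
  ys <- g$sdr_blocks[g$sdr_blocks$type == "y_specific", ]
  on_ys <- s$depth_bins$contig == "chrY" &
    apply(outer(s$depth_bins$start, ys$start, ">=") &
            outer(s$depth_bins$end, ys$end, "<="), 1, any)
  expect_lt(mean(s$depth[on_ys, females]), 1)
  # males retain half depth there
  expect_gt(mean(s$depth[on_ys, !females]), 0.4 * cfg$mean_depth)
  expect_lt(mean(s$depth[on_ys, !females]), 0.6 * cfg$mean_depth)
})

test_that("mean autosomal depth is conserved at megabase scale", {
  cfg <- sim_config(n_autosomes = 1, autosome_length = 2e6,
                    sex_chrom_length = 2e5, sdr_start = 5e4,
                    sdr_end = 1.9e5, block_size = 2e4, bin_size = 2e3,
                    seed = 5)
  s <- simulate_samples(simulate_genome(cfg), cfg)
  auto <- s$depth_bins$contig == "chr1"
  per_ind <- colMeans(s$depth[auto, ])
  expect_true(all(abs(per_ind - cfg$mean_depth) / cfg$mean_depth < 0.02))
})

test_that("gene pair honours truncation and zero-rate identity", {
  gp <- simulate_gene_pair(0, 0, truncation = 2:4, seed = 1)
  expect_equal(length(gp$duplicate_exons), 4)
  expect_identical(gp$duplicate_cds, gp$parent_aligned_cds)
  # parent restricted to kept exons really is the parent subsequence
  ends <- cumsum(gp$parent_exons) * 3
  starts <- c(1, head(ends, -1) + 1)
  kept_nt <- paste(unlist(lapply(gp$kept_exons, function(e)
    substring(gp$parent_cds, starts[e], ends[e]))), collapse = "")
  expect_identical(gp$parent_aligned_cds, kept_nt)
  expect_false(simulate_gene_pair(0.3, 0.1, seed = 1)$saturation_warning)
  expect_true(simulate_gene_pair(1.2, 0.1, seed = 1)$saturation_warning)
})

test_that("NG86 recovers the simulated Ks target", {
  ks <- vapply(1:25, function(s) {
    gp <- simulate_gene_pair(0.35, 0.1, truncation = 2:4, seed = s,
                             n_exons = 7, codons_per_exon = 476)
    ng86_kaks(gp$parent_aligned_cds, gp$duplicate_cds)$Ks[1]
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.35), 0.05)
})
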