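#' Simulation configuration for the synthetic XY-system dataset
#'
#' Builds and validates the parameter set that fully specifies one
#' simulated study: genome geometry, SDR placement, sample sizes,
#' sequencing-depth law, SNP densities, X-Y divergence and repeat
#' enrichment.  Defaults reproduce the study design the package is
#' tested against: 8 males vs 8 females, a ~2 Mbp sex-chromosome pair
#' whose SDR spans 0.5-1.9 Mbp, and 30x mean diploid depth.
#'
#' @param n_autosomes Number of autosomal contigs.
#' @param autosome_length Length of each autosome (bp).
#' @param sex_chrom_length Length of each sex chromosome (bp); X and Y are
#'   simulated at equal, co-linear length.
#' @param sdr_start,sdr_end Half-open SDR interval on the Y contig (bp).
#'   `sdr_start == sdr_end` simulates a null genome with no SDR.
#' @param n_males,n_females Numbers of sequenced XY males and XX females.
#' @param mean_depth Mean diploid (autosomal) read depth per site.
#' @param depth_dispersion Dispersion of per-bin depth: bin depth is drawn
#'   from a gamma mixing law with variance `depth_dispersion * mean^2`
#'   (the overdispersion component of a negative-binomial depth model);
#'   0 gives noise-free depth.
#' @param snp_density Neutral polymorphic-site density (SNPs/bp).
#' @param sdr_divergence Per-site X-Y substitution divergence inside
#'   SDR blocks that retain an X homolog.
#' @param background_divergence Per-site X-Y divergence outside the SDR
#'   (0: the pseudoautosomal region still recombines).
#' @param line_enrichment_factor Fold enrichment of LINE repeat density in
#'   the flank of the sex-determining gene relative to background.
#' @param seed Integer seed; every stochastic stage derives its stream
#'   from this.
#' @param bin_size Depth-bin width (bp); must divide evenly into scan
#'   windows for coverage aggregation.
#' @param block_size Width of the Y-specific / X-diverged mosaic blocks
#'   the SDR is partitioned into (bp).
#' @param y_specific_frac Fraction of SDR blocks that are Y-specific
#'   (no X homolog; female depth ~0) rather than X-diverged.
#' @param repeat_density Genome-background masked fraction per repeat
#'   class.
#' @param sdg_flank Width (bp) of the flank on each side of the
#'   sex-determining gene in which LINE density is enriched.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$sdr_end - cfg$sdr_start   # 1.4 Mbp SDR
sim_config <- function(n_autosomes = 4L,
                       autosome_length = 2e6,
                       sex_chrom_length = 2e6,
                       sdr_start = 5e5,
                       sdr_end = 1.9e6,
                       n_males = 8L,
                       n_females = 8L,
                       mean_depth = 30,
                       depth_dispersion = 0.02,
                       snp_density = 0.005,
                       sdr_divergence = 0.05,
                       background_divergence = 0,
                       line_enrichment_factor = 3,
                       seed = 1L,
                       bin_size = 1e4,
                       block_size = 1e5,
                       y_specific_frac = 0.5,
                       repeat_density = 0.05,
                       sdg_flank = 1e5) {
  cfg <- list(
    n_autosomes = as.integer(n_autosomes),
    autosome_length = as.numeric(autosome_length),
    sex_chrom_length = as.numeric(sex_chrom_length),
    sdr_start = as.numeric(sdr_start),
    sdr_end = as.numeric(sdr_end),
    n_males = as.integer(n_males),
    n_females = as.integer(n_females),
    mean_depth = as.numeric(mean_depth),
    depth_dispersion = as.numeric(depth_dispersion),
    snp_density = as.numeric(snp_density),
    sdr_divergence = as.numeric(sdr_divergence),
    background_divergence = as.numeric(background_divergence),
    line_enrichment_factor = as.numeric(line_enrichment_factor),
    seed = as.integer(seed),
    bin_size = as.numeric(bin_size),
    block_size = as.numeric(block_size),
    y_specific_frac = as.numeric(y_specific_frac),
    repeat_density = as.numeric(repeat_density),
    sdg_flank = as.numeric(sdg_flank)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid sim_config field '%s': %s", field, msg),
           call. = FALSE)
    }
  }
  chk(cfg$n_autosomes >= 1, "n_autosomes", "must be >= 1")
  chk(cfg$autosome_length > 0, "autosome_length", "must be > 0")
  chk(cfg$sex_chrom_length > 0, "sex_chrom_length", "must be > 0")
  chk(cfg$sdr_start >= 0 && cfg$sdr_start <= cfg$sdr_end,
      "sdr_start", "need 0 <= sdr_start <= sdr_end")
  chk(cfg$sdr_end <= cfg$sex_chrom_length, "sdr_end",
      "must be <= sex_chrom_length")
  chk(cfg$n_males >= 1, "n_males", "must be >= 1")
  chk(cfg$n_females >= 1, "n_females", "must be >= 1")
  chk(cfg$mean_depth > 0, "mean_depth", "must be > 0")
  chk(cfg$depth_dispersion >= 0, "depth_dispersion", "must be >= 0")
  for (f in c("snp_density", "sdr_divergence", "background_divergence",
              "y_specific_frac", "repeat_density")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0, 1]")
  }
  chk(cfg$line_enrichment_factor >= 0, "line_enrichment_factor",
      "must be >= 0")
  chk(cfg$bin_size > 0, "bin_size", "must be > 0")
  chk(cfg$block_size > 0, "block_size", "must be > 0")
  chk(cfg$sdg_flank >= 0, "sdg_flank", "must be >= 0")
  invisible(cfg)
}

# Derive a reproducible per-stage seed from the master seed.  Offsets are
# fixed so each stage consumes an independent substream; kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, samples = 211L, pair = 307L, repeats = 401L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) * 977L + offsets[[stage]]) %% 2147483647L
}
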