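# Desk-scale simulation used across unit tests: 200 kb chromosomes with
# the SDR spanning 50-190 kb of the sex pair, 5 kb depth bins.
small_cfg <- function(seed = 1, ...) {
  sim_config(n_autosomes = 4, autosome_length = 2e5,
             sex_chrom_length = 2e5, sdr_start = 5e4, sdr_end = 1.9e5,
             block_size = 2e4, bin_size = 5e3, sdg_flank = 2e4,
             seed = seed, ...)
}

small_windows <- function() make_windows(2e5, 2e4, 1e4)

# sample_set-shaped container for hand-built depth fixtures
depth_fixture <- function(depth, bins, sex) {
  list(depth_bins = bins, depth = depth,
       individuals = data.frame(id = colnames(depth), sex = sex,
                                stringsAsFactors = FALSE))
}
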