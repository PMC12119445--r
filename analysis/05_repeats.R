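#!/usr/bin/env Rscript
# Repeat landscape of the sex contig: per-window class densities and
# the LINE-enrichment contrast between the SDG flank and the
# corresponding flank of its autosomal parent gene.

library(sdrscan)

cfg <- sim_config(seed = 1)
genome <- simulate_genome(cfg)

win <- make_windows(cfg$sex_chrom_length, 2e4, 1e4)
dens <- repeat_density(genome$repeats, win, "chrY")
dir.create("results", showWarnings = FALSE)
write.table(dens, "results/05_repeat_density.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sdg <- genome$genes[genome$genes$gene_id == genome$sdg, ]
par <- genome$genes[genome$genes$gene_id == "amh_a", ]
fl <- 1e5
enr <- region_enrichment(
  genome$repeats,
  list(contig = "chrY", start = max(0, sdg$start - fl),
       end = min(cfg$sex_chrom_length, sdg$end + fl)),
  list(contig = "chr1", start = max(0, par$start - fl),
       end = min(cfg$autosome_length, par$end + fl)),
  "LINE", seed = cfg$seed)
print(enr)

write.table(
  data.frame(class = enr$class, density_sdg_flank = enr$density_a,
             density_parent_flank = enr$density_b, fold = enr$fold,
             p_perm = enr$p_perm, p_fisher = enr$p_fisher),
  "results/05_line_enrichment.tsv", sep = "\t", row.names = FALSE,
  quote = FALSE)
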