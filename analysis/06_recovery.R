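#!/usr/bin/env Rscript
# Parameter-recovery experiment: 20 seeded default simulations (does
# the called SDR match the truth?) and 20 null simulations with no SDR
# (how often is one called anyway?), plus contig-classification
# accuracy under default depth noise.

library(sdrscan)

rec <- recovery_experiment(20, run_config(seed = 1))
nul <- recovery_experiment(20, run_config(sim = list(sdr_start = 0,
                                                     sdr_end = 0),
                                          seed = 501),
                           stages = "scan")

dir.create("results", showWarnings = FALSE)
write.table(rec, "results/06_recovery_default.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(nul, "results/06_recovery_null.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("SDR recovery (Jaccard >= 0.9): %d/20 runs\n",
            sum(rec$jaccard >= 0.9)))
cat(sprintf("mean Jaccard: %.3f; boundary errors within one step: %s\n",
            mean(rec$jaccard),
            all(abs(c(rec$start_error, rec$end_error)) <= 1e4)))
cat(sprintf("classification accuracy: %.3f\n", mean(rec$accuracy)))
cat(sprintf("null false-positive SDR calls: %d/20 runs\n",
            sum(nul$called_sdr)))
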