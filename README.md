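# sdrscan

Mapping a sex-determining region (SDR) and its candidate
sex-determining gene (SDG) in a young XY sex-chromosome system from
resequencing data of known-sex individuals.

In many fishes the sex chromosomes are barely differentiated: the Y
carries a short non-recombining region — often created by the
translocation of a truncated duplicate of an autosomal gene (an
*amh*-type duplicate is a recurrent example) — while the rest of the
pair still recombines. Locating that region from sequence data uses a
handful of complementary signals, all implemented here for users doing
sex-chromosome genomics at the assembly-plus-resequencing stage:

* **Depth-ratio linkage classification.** For each individual, per-bin
  read depth is normalized by that individual's overall (median)
  genomic depth. Y-linked contigs show male ratios of ~0.3–0.7 (one
  copy) with females depth-depleted or carrying male-specific marker
  hits; X-linked contigs show male half depth with female ratios near
  1; autosomes sit near 1 in both sexes.
* **Windowed sex-association scan.** At each SNP the sex × allele 2×2
  table is tested with a two-sided Fisher exact test, plotted as
  −log10 *p*, together with Hudson's Fst estimator
  (numerator (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1), denominator
  p₁(1−p₂) + p₂(1−p₁), combined per window as ratio of sums).
* **Per-sex coverage and X–Y divergence windows.** Hemizygous
  (Y-specific) sequence shows male ~0.5× / female ~0 coverage; diverged
  but still homologous X–Y sequence shows d_XY > 0 (p-distance, with
  optional Jukes–Cantor correction −(3/4)·ln(1 − (4/3)p)).
* **Rule-based SDR calling.** A window qualifies if sex-associated
  SNPs (−logP > 2) are enriched in it, or if it shows the
  female-absent/male-half coverage signature, or d_XY above threshold;
  qualifying windows are merged (gap tolerance one window) into
  maximal candidate intervals.
* **Marker presence/absence association** across a panel (e.g. the SDG
  present in all males, absent in all females), with a perfect
  separation flag.
* **Duplicate-gene molecular evolution.** Nei–Gojobori (1986) Ka/Ks
  with full substitution-pathway averaging, per exon and whole gene;
  selection-regime classification by an exact binomial comparison of
  nonsynonymous vs synonymous differences; duplication dating
  T = Ks/(2r) for a user-supplied synonymous rate r; frameshift
  classification of coding indels.
* **Repeat windows.** Per-window repeat-class densities (RepeatMasker
  `.out` or BED input) and LINE-enrichment contrasts between the SDG
  flank and the matching autosomal flank (fold change, exact bp-table
  test with an autocorrelation caveat, and a seeded block-permutation
  test).

A fully seeded synthetic-data generator (`sim_config()`,
`simulate_genome()`, `simulate_samples()`, `simulate_gene_pair()`,
`write_dataset()`) emulates the whole XY design — SDR mosaic of
Y-specific and X-diverged blocks, 8 males + 8 females at 30×,
negative-binomial-type depth noise, LINE-enriched SDG flank — with
known ground truth, so every stage is testable at desk scale.

## Worked example

```r
library(sdrscan)

cfg <- run_config(seed = 1)       # 2 Mbp sex pair, SDR 0.5-1.9 Mbp,
rep <- run_pipeline(cfg)          # 20/10 kbp windows, 8M + 8F at 30x
print(rep)
#> pipeline_report
#>   linkage: accuracy 1.000 over 6 contigs
#>   scan: 1 SDR interval(s), Jaccard vs truth 0.986
#>   marker: p = 0.000155, perfect separation = TRUE
#>   kaks: Ka 0.093 Ks 0.332 omega 0.280 (purifying)
#>   repeats: LINE fold 2.56, perm p 0.0030
```

Reading the numbers: all six contigs (four autosomes, X, Y) are
classified to their true linkage class from depth ratios alone; the
scan merges the qualifying windows into a single called interval,
[490 kbp, 1 910 kbp), overlapping the simulated truth
[500 kbp, 1 900 kbp) with Jaccard 0.986 (each boundary within one
window step); the candidate gene is present in all 8 males and no
female (two-sided Fisher exact p = 1.6e-4, the smallest value 8-vs-8
presence data can attain); and the truncated duplicate evolves under
relaxed purifying selection (ω = 0.28) with Ks ≈ 0.33, which at an
assumed synonymous rate of 3.5e-9 subs/site/year dates the duplication
to ~50 My.

The `analysis/` directory steps through the same workflow as numbered
scripts (simulate → classify → scan → molecular evolution → repeats →
recovery experiment), writing tables under `results/`.

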