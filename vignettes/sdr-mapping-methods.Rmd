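---
title: "Methods: locating a sex-determining region in an XY system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating a sex-determining region in an XY system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrscan)
```

# The problem and the model

A young XY system consists of a mostly recombining chromosome pair with
a short sex-determining region (SDR) on the Y where recombination with
the X has ceased. Inside that region two kinds of sequence coexist:

* **Y-specific sequence** with no X homolog — typically including a
  translocated, truncated duplicate of an autosomal gene acting as the
  candidate sex-determining gene (SDG). XY males carry one copy
  (sequencing depth ≈ half the diploid depth); XX females carry none
  (depth ≈ 0, genotypes missing).
* **X-diverged sequence** that still has an X homolog but has
  accumulated fixed X–Y differences. Every such fixed difference is a
  perfectly sex-associated SNP: males (one X, one Y) are heterozygous,
  females (two X copies) homozygous.

Outside the SDR the pseudoautosomal region recombines, so X and Y are
effectively identical and no signal is expected. `sdrscan` turns each
of these expectations into a statistic, scans them in sliding windows,
and calls SDR intervals by rule.

# Statistics and their conventions

**Depth normalization.** Each individual's per-bin depth is divided by
that individual's genome-wide *median* bin depth ("overall genomic
depth"). The median is robust to the sex-linked minority of bins and
makes the profile invariant to per-library sequencing effort. An
important geometric caveat, discovered at desk scale: if sex-linked
bins approach half of all bins, the pooled median slides into the lower
tail of the diploid depth cluster and inflates every ratio. The
simulator therefore defaults to four autosomes against one sex pair, so
diploid bins are a clear majority — the situation in any real genome,
where sex chromosomes are a small fraction of the assembly.

**Linkage classification.** With normalized male ratio $m$ and female
ratio $f$ per contig: Y-linked iff $m \in [0.3, 0.7]$ and
($f \le 0.1$ or male-specific marker hits are present); X-linked iff
$m \in [0.3, 0.7]$, $f \in (0.1, 1.3]$ and no marker hits; autosomal
iff $m, f \in [0.7, 1.3]$; otherwise *ambiguous* — contigs are never
silently dropped. The half-depth band 0.3–0.7 is the classical
criterion for single-copy sequence; the ambiguous class is this
package's addition (a classifier should have a reject option). Marker
evidence takes precedence over female depth because a Y contig that
retains some X-homologous sequence shows intermediate female coverage
(the default simulation's Y contig has $f \approx 0.42$ for exactly
this reason).

**Sex association.** Per SNP, allele counts are cross-tabulated by sex
and tested with the two-sided Fisher exact test (point-probability
rule, as in `stats::fisher.test`); the statistic plotted and
thresholded is $-\log_{10} p$. With 8 males vs 8 females the smallest
attainable two-sided p at a fixed X–Y difference site (males 8/8
ref/alt, females 0/16) is ~2.4e-3 ($-\log P \approx 2.6$), and a
presence/absence marker separating the sexes perfectly reaches
1.55e-4. Sites with a whole sex missing (Y-specific hemizygous sites)
are excluded from testing and tallied separately.

**Fst.** Hudson's two-population estimator, chosen because it is
well-behaved at small, unequal sample sizes and has an unambiguous
ratio-of-sums windowed form: per-window
$\mathrm{Fst} = \sum_i N_i / \sum_i D_i$ with
$N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
and $D = p_1(1-p_2) + p_2(1-p_1)$. Reported values are clipped to
$[0,1]$ (the raw value is kept alongside); a fixed difference gives
exactly 1 and equal frequencies exactly 0.

**Windows.** Half-open windows of width $w$ at step $s$ tile
$[0, L)$; the last window is truncated at the contig end and no window
starts past the point where the previous one already reaches the end.
Field-standard geometry is 50 kbp / 25 kbp; the desk-scale default is
20 kbp / 10 kbp so a full run takes seconds.

**X–Y divergence.** d_XY is the p-distance (mismatches per aligned
site) between X and Y over an alignment map of co-linear segments —
supplied by the simulator's truth, or by any pairwise aligner in real
use. Jukes–Cantor correction $-\frac{3}{4}\ln(1-\frac{4}{3}p)$ is
optional and skipped (with a saturation flag) at $p \ge 0.75$. Windows
with fewer than `min_aligned_sites` (default 100) aligned positions are
null rather than zero.

**SDR calling.** A window qualifies if any of:

1. *association enrichment*: its best SNP exceeds $-\log P > 2$ **and**
   at least `assoc_frac_min` (default 10%) of its tested SNPs do;
2. *female absence*: female coverage < 0.1 with male coverage in
   [0.3, 0.7];
3. *divergence*: d_XY above `dxy_min` (default 0 — the pseudoautosomal
   background has no fixed differences).

Qualifying windows are merged with a gap tolerance of one window and
ranked by summed evidence. The enrichment component of rule 1 is a
deliberate design decision: a window holding ~100 tested SNPs sees a
single $p \le 0.01$ by chance far too often (the per-site null
probability is about $10^{-3}$ under the discrete Fisher null, i.e.
roughly one window in ten), so requiring a lone maximum would call
spurious SDRs on nearly every null genome. Requiring the *fraction* of
sub-0.01 SNPs to reach 10% keeps the null false-positive probability
negligible while leaving true SDR windows — where almost every fixed
X–Y difference tests at the attainable minimum — untouched. No
multiple-testing correction is applied to the per-site p-values (the
Manhattan-style reading thresholds raw $-\log P$); a Bonferroni-style
interpretation can be imposed by raising `neg_log_p_min`.

**NG86 Ka/Ks.** Synonymous site opportunities per codon are the
fractions of the three possible changes per position that preserve the
amino acid; changes creating a stop codon count as nonsynonymous, which
keeps $N + S = 3 \times \text{codons}$ exactly. Observed differences in
codons differing at 2–3 positions are averaged over all substitution
pathways; pathways through a stop codon are excluded, falling back to
all pathways only if every ordering is blocked. $p_N, p_S$ are
Jukes–Cantor corrected to Ka, Ks; $p \ge 0.75$ is returned uncorrected
with a saturation flag. NG86 was chosen over ML codon models because it
is fully specifiable and oracle-checkable: the test suite compares
every one of the 64×64 codon pairs against an independent brute-force
pathway enumeration.

**Selection classes.** *positive* iff $\omega > 1$ and a one-sided
exact binomial test of the nonsynonymous share of differences against
the site-proportion expectation $N/(N+S)$ rejects at $\alpha = 0.05$;
*purifying* symmetric with $\omega < 1$; otherwise *neutral*;
*undefined* at $K_s = 0$. The thresholds are this package's, not a
literature standard — "relaxed purifying selection" has no canonical
test, so the class is reported together with the counts it came from.

**Dating.** $T = K_s / (2r)$ with $r$ in substitutions/site/year,
reported in My. $r$ is a required analysis input with *no default*:
dates are only as good as the clock, and silently assuming one would
manufacture false precision. The analysis scripts pass 3.5e-9 — a
typical teleost nuclear magnitude chosen for illustration (it maps
$K_s = 0.35$ to exactly 50 My).

**Repeat enrichment.** Same-class intervals are merged before any
density computation (idempotent by construction). The SDG-flank
contrast (default flank 100 kbp each side, configurable — no standard
width exists) reports the density fold change plus two p-values: an
exact test on the masked/unmasked bp table, printed with an explicit
caveat that base pairs are autocorrelated so this p is anti-
conservative, and a seeded block-permutation p (10 kbp blocks, 1000
label shuffles) which is the one to believe.

# What the simulator emulates — and what it does not

`simulate_genome()`/`simulate_samples()` generate: a configurable
number of autosomes plus an equal-length, co-linear X/Y pair; an SDR
partitioned into 100 kbp blocks, each Y-specific (probability
`y_specific_frac`, default 0.5) or X-diverged (per-site divergence
`sdr_divergence`, default 0.05); a 7-exon autosomal parent gene and its
4-exon Y duplicate (exons 2–4 lost) placed in a Y-specific block; LINE
repeats enriched `line_enrichment_factor`-fold (default 3) in the ±100
kbp SDG flank over a 5% per-class background; 8 males and 8 females
with 30× diploid depth; neutral SNPs at 0.005/bp with uniform allele
frequencies under Hardy–Weinberg sampling; and every fixed X–Y
difference surfacing as a male-heterozygous SNP on the Y coordinate.

Depth noise is gamma-multiplicative per bin with variance
$d \cdot \mu^2$ — the mixing distribution of a negative-binomial read
count model — so `depth_dispersion = 0` gives exact expectations (used
by the noise-free classification tests). The default $d = 0.02$
(per-10 kbp-bin CV ≈ 14%) matches the scale of GC/mappability-driven
coverage variation in short-read data.

The scan runs on the SDR-carrying sex contig's coordinates, where all
four signals coexist: Y-specific blocks show the coverage signature,
X-diverged blocks the association and d_XY signatures. (A real analysis
may instead scan the X, with male-mapped Y reads creating the
heterozygous signal; the statistics are identical, only the coordinate
frame differs.)

Deliberately **not** emulated: read-level data (no FASTQ/BAM — depth
and genotypes are generated directly, so mapping bias, genotyping
error and allelic dropout are absent); recombination maps and LD;
demographic history (allele frequencies are i.i.d.); assembly errors.
Passing tests therefore demonstrate correctness of the statistics and
calling logic under the stated generative model, not robustness to
mapping artifacts in real libraries — on real data the thresholds
(`assoc_frac_min`, `female_absent_max`, `dxy_min`) are the knobs that
absorb those artifacts.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; 1-based only
  in VCF/GFF3 serialization.
* All randomness flows from one master seed through fixed per-stage
  offsets, so stages are individually reproducible and a rerun is
  byte-identical.
* Monomorphic sites: $p = 1$, Fst 0, flagged. Sites lacking a sex:
  excluded, counted. Windows without SNPs/bins/alignment: `NA`, never
  0. Empty SDR call: zero-row interval table that prints "scanned,
  none found".
* `simulate_gene_pair()` places substitutions so the *observed*
  difference proportions equal the Jukes–Cantor forward map
  $\frac{3}{4}(1 - e^{-4K/3})$ of the targets, each event creating
  exactly one new differing position and never a stop codon; NG86 + JC
  then recovers the targets without bias (mean Ks within 5% of a 0.35
  target at 10 kb over 100 replicates, verified in the tests).
* The problem sizes used throughout testing were chosen so the full
  suite runs in minutes on one core: 2 Mbp sex pair with 0.5–1.9 Mbp
  SDR and 20/10 kbp windows for recovery experiments (20 default + 20
  null seeds), 200 kbp chromosomes for unit fixtures, 10 kb gene pairs
  for estimator calibration. Study-scale geometry (tens of Mbp, 50/25
  kbp windows) is reached through the same configuration fields.

# Known limitations

* The Fisher test on allele counts treats the 2n alleles as
  independent; with strong inbreeding or genotyping error a
  genotype-level test would differ. Mixed-model GWAS and kinship
  correction are out of scope.
* Hemizygous male genotypes are encoded as diploid homozygotes (the
  VCF convention of most callers), slightly inflating male allele
  counts at X/Y sites.
* The exact bp-table enrichment p is reported for comparability but is
  anti-conservative by construction; rely on the permutation p.
* NG86 underestimates rates under strong codon-usage or
  transition/transversion bias relative to ML methods; for the
  desk-scale questions here (relative exon patterns, order-of-magnitude
  dating) that bias is immaterial, and the estimator's exactness is
  what makes it fully testable.
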