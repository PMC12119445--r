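Package: sdrscan
Title: Sex-Determining Region Mapping from Depth, Association and
    Divergence Scans in an XY System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the sex-determining region (SDR) and a candidate
    Y-linked sex-determining gene in an XY sex-chromosome system.
    Classifies contigs as autosomal, X-linked or Y-linked from
    per-individual sequencing-depth ratios and male-specific marker
    hits; runs sliding-window scans of sex-association (Fisher exact
    -logP), Hudson Fst, per-sex normalized coverage and X-Y nucleotide
    divergence; calls SDR intervals by rule; tests presence/absence
    markers for sex association; and analyses duplicate-gene molecular
    evolution with Nei-Gojobori (1986) Ka/Ks, selection-regime
    classification and Ks-based duplication dating. A seeded synthetic
    XY-system data generator (genome, annotations, depths, genotypes,
    duplicate coding sequences) with known ground truth makes the whole
    pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
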