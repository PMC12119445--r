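#' Simulate resequenced individuals over a simulated genome
#'
#' Draws `n_males` XY males and `n_females` XX females with per-bin read
#' depths and per-site genotypes that follow the hemizygosity logic of an
#' XY system:
#'
#' * autosomal bins: expectation `mean_depth` in both sexes;
#' * X and Y bins: expectation `mean_depth/2` in males (one copy each);
#' * female depth is `mean_depth/2` over pseudoautosomal sequence (reads
#'   split between the co-assembled X and Y), `mean_depth` over
#'   X-diverged SDR blocks and over the SDR-homologous stretch of the X,
#'   and ~0 over Y-specific blocks;
#' * X-Y fixed differences inside diverged SDR blocks surface as
#'   sex-associated SNPs (males heterozygous X/Y, females homozygous X);
#' * Y-specific sites are hemizygous: females are always missing (`./.`),
#'   a property asserted before return.
#'
#' Per-bin depth noise is gamma-distributed with variance
#' `depth_dispersion * mean^2` (the overdispersion component of a
#' negative-binomial read-count model); `depth_dispersion = 0` gives the
#' exact expectations.
#'
#' @param genome A `genome_model` from [simulate_genome()].
#' @param cfg The same [sim_config()] used to build `genome`.
#' @return A list of class `sample_set`: `individuals` (id, sex), `sites`
#'   (contig, pos, ref, alt, type), `geno` (sites x individuals ALT-dosage
#'   matrix, `NA` = missing), `depth_bins` + `depth` (bins x individuals
#'   raw depth), `marker_presence` (per-individual presence of the SDG
#'   marker), `marker_hits` (per-contig marker counts).
#' @export
simulate_samples <- function(genome, cfg = genome$cfg) {
  stopifnot(inherits(genome, "genome_model"))
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "samples"))

  individuals <- data.frame(
    id = c(sprintf("M%02d", seq_len(cfg$n_males)),
           sprintf("F%02d", seq_len(cfg$n_females))),
    sex = c(rep("M", cfg$n_males), rep("F", cfg$n_females)),
    stringsAsFactors = FALSE
  )
  n_ind <- nrow(individuals)
  is_male <- individuals$sex == "M"

  ## ---- depth expectations per contig segment --------------------------
  segs <- depth_segments(genome)
  bins <- make_depth_bins(genome$contigs, cfg$bin_size)
  bin_ratio <- segment_ratio_per_bin(bins, segs)

  mu <- cbind(matrix(bin_ratio$m_ratio, nrow(bins), sum(is_male)),
              matrix(bin_ratio$f_ratio, nrow(bins), sum(!is_male))) *
    cfg$mean_depth
  if (cfg$depth_dispersion > 0) {
    d <- cfg$depth_dispersion
    depth <- matrix(0, nrow(bins), n_ind)
    pos <- mu > 0
    depth[pos] <- rgamma(sum(pos), shape = 1 / d, scale = mu[pos] * d)
  } else {
    depth <- mu
  }
  colnames(depth) <- individuals$id

  ## ---- sites and genotypes -------------------------------------------
  seq_chars <- lapply(as.character(genome$sequences), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  blocks <- genome$sdr_blocks
  div_blocks <- blocks[blocks$type == "diverged", , drop = FALSE]
  ys_blocks <- blocks[blocks$type == "y_specific", , drop = FALSE]

  site_list <- list()
  geno_list <- list()

  add_sites <- function(contig, pos0, type, geno) {
    if (!length(pos0)) return()
    ref <- seq_chars[[contig]][pos0 + 1L]
    alt <- mutate_base(ref)
    site_list[[length(site_list) + 1L]] <<- data.frame(
      contig = contig, pos = pos0, ref = ref, alt = alt, type = type,
      stringsAsFactors = FALSE)
    geno_list[[length(geno_list) + 1L]] <<- geno
  }

  diploid_geno <- function(n_sites, hemi_male = FALSE, hemi_female = FALSE) {
    if (!n_sites) return(matrix(NA_integer_, 0, n_ind))
    p <- runif(n_sites, 0.05, 0.95)
    g <- matrix(NA_integer_, n_sites, n_ind)
    for (j in seq_len(n_ind)) {
      hemi <- if (is_male[j]) hemi_male else hemi_female
      g[, j] <- if (hemi) 2L * rbinom(n_sites, 1L, p) else
        rbinom(n_sites, 2L, p)
    }
    g
  }

  sample_pos <- function(from, to, density, exclude = integer(0)) {
    len <- to - from
    n <- rbinom(1, max(0, round(len)), density)
    if (n <= 0) return(integer(0))
    p <- from + sample.int(len, min(n, len)) - 1L
    sort(setdiff(p, exclude))
  }

  for (ci in seq_len(nrow(genome$contigs))) {
    ctg <- genome$contigs$contig[ci]
    clen <- genome$contigs$length[ci]
    cls <- genome$contigs$true_class[ci]
    if (cls == "autosomal") {
      pos <- sample_pos(0, clen, cfg$snp_density)
      add_sites(ctg, pos, "neutral", diploid_geno(length(pos)))
    } else if (cls == "X_linked") {
      # males carry one X: hemizygous (homozygous-looking) calls
      pos <- sample_pos(0, clen, cfg$snp_density)
      add_sites(ctg, pos, "neutral",
                diploid_geno(length(pos), hemi_male = TRUE))
    } else {
      ## chrY: fixed X-Y differences in diverged blocks -> sex-associated
      x_chars <- seq_chars[["chrX"]]
      y_chars <- seq_chars[["chrY"]]
      assoc_pos <- integer(0)
      for (bi in seq_len(nrow(div_blocks))) {
        rng <- (div_blocks$start[bi] + 1L):div_blocks$end[bi]
        assoc_pos <- c(assoc_pos, rng[x_chars[rng] != y_chars[rng]] - 1L)
      }
      if (length(assoc_pos)) {
        ref <- y_chars[assoc_pos + 1L]
        alt <- x_chars[assoc_pos + 1L]     # ALT is the X allele
        g <- matrix(2L, length(assoc_pos), n_ind)   # females: X/X hom ALT
        g[, is_male] <- 1L                          # males: Y/X het
        site_list[[length(site_list) + 1L]] <- data.frame(
          contig = ctg, pos = assoc_pos, ref = ref, alt = alt,
          type = "sex_assoc", stringsAsFactors = FALSE)
        geno_list[[length(geno_list) + 1L]] <- g
      }
      ## Y-specific blocks: male-only hemizygous polymorphism
      for (bi in seq_len(nrow(ys_blocks))) {
        pos <- sample_pos(ys_blocks$start[bi], ys_blocks$end[bi],
                          cfg$snp_density)
        if (!length(pos)) next
        p <- runif(length(pos), 0.05, 0.95)
        g <- matrix(NA_integer_, length(pos), n_ind)
        for (j in which(is_male)) g[, j] <- 2L * rbinom(length(pos), 1L, p)
        add_sites(ctg, pos, "y_specific", g)
      }
      ## shared polymorphism everywhere Y aligns to X
      shared <- IRanges::setdiff(
        IRanges::IRanges(1, clen),
        IRanges::IRanges(ys_blocks$start + 1, ys_blocks$end))
      for (si in seq_along(shared)) {
        pos <- sample_pos(IRanges::start(shared)[si] - 1L,
                          IRanges::end(shared)[si], cfg$snp_density,
                          exclude = assoc_pos)
        add_sites(ctg, pos, "neutral", diploid_geno(length(pos)))
      }
    }
  }

  sites <- do.call(rbind, site_list)
  geno <- do.call(rbind, geno_list)
  ord <- order(match(sites$contig, genome$contigs$contig), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL
  colnames(geno) <- individuals$id

  # hemizygosity contract: no female carries a call at a Y-specific site
  stopifnot(all(is.na(geno[sites$type == "y_specific", !is_male])))

  marker_presence <- setNames(!is.na(genome$sdg) & is_male, individuals$id)
  marker_hits <- setNames(integer(nrow(genome$contigs)),
                          genome$contigs$contig)
  if (!is.na(genome$sdg)) {
    sdg_ctg <- genome$genes$contig[genome$genes$gene_id == genome$sdg]
    marker_hits[sdg_ctg] <- 1L
  }

  structure(list(
    individuals = individuals,
    sites = sites,
    geno = geno,
    depth_bins = bins,
    depth = depth,
    marker_presence = marker_presence,
    marker_hits = marker_hits,
    cfg = cfg
  ), class = "sample_set")
}

#' @exportS3Method base::print
print.sample_set <- function(x, ...) {
  cat("sample_set:", sum(x$individuals$sex == "M"), "males +",
      sum(x$individuals$sex == "F"), "females;",
      nrow(x$sites), "SNP sites;", nrow(x$depth_bins), "depth bins\n")
  print(table(x$sites$type))
  invisible(x)
}

# expected (male, female) depth ratios by contig segment
depth_segments <- function(genome) {
  cfg <- genome$cfg
  out <- list()
  for (ci in seq_len(nrow(genome$contigs))) {
    ctg <- genome$contigs$contig[ci]
    clen <- genome$contigs$length[ci]
    cls <- genome$contigs$true_class[ci]
    if (cls == "autosomal") {
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = 0, end = clen, m_ratio = 1, f_ratio = 1)
    } else if (cls == "X_linked") {
      # SDR-homologous stretch of the X: all female reads map home
      sdr <- c(cfg$sdr_start, cfg$sdr_end)
      seg <- data.frame(contig = ctg,
                        start = c(0, sdr[1], sdr[2]),
                        end = c(sdr[1], sdr[2], clen),
                        m_ratio = 0.5,
                        f_ratio = c(0.5, 1, 0.5))
      out[[length(out) + 1L]] <- seg[seg$end > seg$start, ]
    } else {
      blocks <- genome$sdr_blocks
      par <- IRanges::setdiff(IRanges::IRanges(1, clen),
                              IRanges::IRanges(blocks$start + 1, blocks$end))
      seg <- data.frame(contig = ctg, start = IRanges::start(par) - 1,
                        end = IRanges::end(par), m_ratio = 0.5,
                        f_ratio = 0.5)
      if (nrow(blocks)) {
        seg <- rbind(seg, data.frame(
          contig = ctg, start = blocks$start, end = blocks$end,
          m_ratio = 0.5,
          f_ratio = ifelse(blocks$type == "y_specific", 0, 1)))
      }
      out[[length(out) + 1L]] <- seg[order(seg$start), ]
    }
  }
  do.call(rbind, out)
}

make_depth_bins <- function(contigs, bin_size) {
  out <- lapply(seq_len(nrow(contigs)), function(ci) {
    st <- seq(0, contigs$length[ci] - 1, by = bin_size)
    data.frame(contig = contigs$contig[ci], start = st,
               end = pmin(st + bin_size, contigs$length[ci]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# overlap-length-weighted expected ratio for each bin
segment_ratio_per_bin <- function(bins, segs) {
  m <- numeric(nrow(bins))
  f <- numeric(nrow(bins))
  for (ctg in unique(bins$contig)) {
    bi <- which(bins$contig == ctg)
    si <- which(segs$contig == ctg)
    br <- IRanges::IRanges(bins$start[bi] + 1, bins$end[bi])
    sr <- IRanges::IRanges(segs$start[si] + 1, segs$end[si])
    ov <- IRanges::findOverlaps(br, sr)
    w <- IRanges::width(IRanges::pintersect(
      br[S4Vectors::queryHits(ov)], sr[S4Vectors::subjectHits(ov)]))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    wsum <- rowsum(w, qh)                       # rows sorted by bin index
    m[bi] <- rowsum(w * segs$m_ratio[si][sh], qh) / wsum
    f[bi] <- rowsum(w * segs$f_ratio[si][sh], qh) / wsum
  }
  data.frame(m_ratio = m, f_ratio = f)
}
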