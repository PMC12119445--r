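#' Simulate a duplicate gene pair with known Ka and Ks
#'
#' Builds a random stop-free parent CDS partitioned into exons, derives a
#' duplicate by deleting the `truncation` exons (emulating a translocated,
#' truncated duplicate such as a Y-borne copy of an autosomal gene), then
#' places synonymous and nonsynonymous substitutions so that the expected
#' *observed* difference proportions equal the Jukes-Cantor forward map
#' of the targets, `p = (3/4)(1 - exp(-(4/3) K))`.  NG86 estimation with
#' JC correction therefore recovers `target_ks`/`target_ka` without bias
#' at sufficient length.  Substitutions never revert a site to the
#' parental base and never create stop codons.
#'
#' @param target_ks,target_ka Target synonymous / nonsynonymous
#'   substitutions per site (>= 0).  Targets > 1 expected
#'   substitution/site set `saturation_warning`.
#' @param truncation Integer indices of parent exons deleted from the
#'   duplicate (e.g. `2:4` turns a 7-exon parent into a 4-exon copy).
#' @param seed Integer seed.
#' @param n_exons Number of parent exons.
#' @param codons_per_exon Codons per exon.
#' @return A list of class `gene_pair`: `parent_cds`, `duplicate_cds`,
#'   `parent_aligned_cds` (parent restricted to retained exons, i.e. the
#'   codon-level alignment partner of the duplicate), `parent_exons` and
#'   `duplicate_exons` (codon lengths), `kept_exons`, `true_ks`,
#'   `true_ka`, `saturation_warning`.
#' @export
#' @examples
#' gp <- simulate_gene_pair(0.35, 0.1, truncation = 2:4, seed = 1)
#' length(gp$duplicate_exons)  # 4 exons left of 7
simulate_gene_pair <- function(target_ks, target_ka,
                               truncation = integer(0), seed = 1L,
                               n_exons = 7L, codons_per_exon = 60L) {
  if (target_ks < 0 || target_ka < 0) {
    stop("substitution targets must be >= 0", call. = FALSE)
  }
  if (length(truncation) && (any(truncation < 1) || any(truncation > n_exons))) {
    stop("truncation must index parent exons", call. = FALSE)
  }
  set.seed(stage_seed(seed, "pair"))
  tab <- ng86_tables()
  sense <- tab$codons[tab$aa != "*"]

  parent_exons <- rep(as.integer(codons_per_exon), n_exons)
  parent <- sample(sense, sum(parent_exons), replace = TRUE)

  kept <- setdiff(seq_len(n_exons), truncation)
  ends <- cumsum(parent_exons)
  starts <- c(1, head(ends, -1) + 1)
  keep_idx <- unlist(lapply(kept, function(e) starts[e]:ends[e]))
  dup <- parent[keep_idx]
  par_aln <- dup                       # pre-divergence copy of the parent

  S <- sum(tab$syn_sites[match(dup, tab$codons)])
  N <- 3 * length(dup) - S
  p_target <- function(k) 0.75 * (1 - exp(-4 * k / 3))
  n_syn <- stochastic_round(S * p_target(target_ks))
  n_non <- stochastic_round(N * p_target(target_ka))

  events <- sample(c(rep("S", n_syn), rep("N", n_non)))
  for (ev in events) {
    dup <- apply_substitution(dup, par_aln, ev == "S", tab)
  }

  structure(list(
    parent_cds = paste(parent, collapse = ""),
    duplicate_cds = paste(dup, collapse = ""),
    parent_aligned_cds = paste(par_aln, collapse = ""),
    parent_exons = parent_exons,
    duplicate_exons = parent_exons[kept],
    kept_exons = kept,
    true_ks = target_ks,
    true_ka = target_ka,
    saturation_warning = target_ks > 1 || target_ka > 1
  ), class = "gene_pair")
}

#' @exportS3Method base::print
print.gene_pair <- function(x, ...) {
  cat("gene_pair:", length(x$parent_exons), "exon parent,",
      length(x$duplicate_exons), "exon duplicate;",
      "true Ks =", x$true_ks, ", true Ka =", x$true_ka, "\n")
  if (x$saturation_warning) cat("  warning: substitution target > 1/site\n")
  invisible(x)
}

stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + (runif(length(x)) < (x - f)))
}

# one substitution event: uniformly pick a codon with an available move
# of the requested class, then a uniform move.  A move is a single-base
# change at a not-yet-diverged position (so every event creates exactly
# one new observed difference) that does not create a stop codon.
apply_substitution <- function(dup, par_aln, synonymous, tab) {
  bases <- c("T", "C", "A", "G")
  for (tries in seq_len(10 * length(dup))) {
    i <- sample.int(length(dup), 1L)
    cur <- strsplit(dup[i], "")[[1]]
    par <- strsplit(par_aln[i], "")[[1]]
    aa_cur <- tab$aa[match(dup[i], tab$codons)]
    moves <- list()
    for (p in which(cur == par)) {
      for (b in setdiff(bases, cur[p])) {
        alt <- cur
        alt[p] <- b
        alt_cd <- paste(alt, collapse = "")
        aa_alt <- tab$aa[match(alt_cd, tab$codons)]
        if (aa_alt == "*") next
        if ((aa_alt == aa_cur) == synonymous) {
          moves[[length(moves) + 1L]] <- alt_cd
        }
      }
    }
    if (length(moves)) {
      dup[i] <- moves[[sample.int(length(moves), 1L)]]
      return(dup)
    }
  }
  stop("no available substitution of the requested class", call. = FALSE)
}
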