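#' @name ng86
#' @title Nei-Gojobori (1986) Ka/Ks estimation
#'
#' @description
#' Counting-method estimation of nonsynonymous (Ka) and synonymous (Ks)
#' substitutions per site between two in-frame coding sequences.
#' Synonymous/nonsynonymous site opportunities are computed per codon as
#' the fraction of the three possible single-base changes at each
#' position that preserve the amino acid (changes creating a stop codon
#' count as nonsynonymous, so `N + S = 3 x codons` exactly) and averaged
#' over the two sequences.  Observed differences in codons that differ
#' at more than one position are averaged over all substitution
#' pathways (orderings of the single-base steps); pathways passing
#' through a stop codon are excluded unless every pathway is blocked.
#' Proportions are Jukes-Cantor corrected,
#' `K = -(3/4) log(1 - (4/3) p)`, with `p >= 0.75` flagged saturated and
#' left uncorrected.
NULL

.ng86_cache <- new.env(parent = emptyenv())

codon_universe <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b,
                  function(ab, c) paste0(ab, c)))
}

# per-codon tables: syn-site counts, and pathway-averaged per-pair
# (Sd, Nd) for all 64 x 64 ordered codon pairs.  Built once per session.
ng86_tables <- function() {
  if (!is.null(.ng86_cache$tab)) return(.ng86_cache$tab)
  codons <- codon_universe()
  gc_map <- Biostrings::GENETIC_CODE[codons]
  aa <- unname(gc_map)
  bases <- c("T", "C", "A", "G")

  syn_sites <- numeric(64)
  for (i in seq_len(64)) {
    cd <- strsplit(codons[i], "")[[1]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, cd[p])) {
        alt <- cd
        alt[p] <- b
        alt_cd <- paste(alt, collapse = "")
        if (aa[match(alt_cd, codons)] == aa[i] && aa[i] != "*") s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }

  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))

  Sd <- matrix(0, 64, 64)
  Nd <- matrix(0, 64, 64)
  for (i in seq_len(64)) {
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(64)) {
      if (i == j) next
      cj <- strsplit(codons[j], "")[[1]]
      dpos <- which(ci != cj)
      d <- length(dpos)
      pm <- perms[[as.character(d)]]
      path_s <- numeric(0)
      path_n <- numeric(0)
      path_ok <- logical(0)
      for (r in seq_len(nrow(pm))) {
        cur <- ci
        s <- 0
        n <- 0
        ok <- TRUE
        for (step in dpos[pm[r, ]]) {
          nxt <- cur
          nxt[step] <- cj[step]
          a1 <- aa[match(paste(cur, collapse = ""), codons)]
          a2 <- aa[match(paste(nxt, collapse = ""), codons)]
          if (a1 == a2 && a1 != "*") s <- s + 1 else n <- n + 1
          cur <- nxt
          # intermediate (non-terminal) stop codon blocks the pathway
          if (a2 == "*" && !identical(cur, cj)) ok <- FALSE
        }
        path_s <- c(path_s, s)
        path_n <- c(path_n, n)
        path_ok <- c(path_ok, ok)
      }
      use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
      Sd[i, j] <- mean(path_s[use])
      Nd[i, j] <- mean(path_n[use])
    }
  }
  .ng86_cache$tab <- list(codons = codons, aa = aa, syn_sites = syn_sites,
                          Sd = Sd, Nd = Nd)
  .ng86_cache$tab
}

split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  if (nchar(seq) %% 3 != 0) {
    stop("sequence length must be divisible by 3", call. = FALSE)
  }
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori Ka/Ks between two aligned coding sequences
#'
#' @param seq_a,seq_b In-frame aligned nucleotide sequences of equal
#'   length divisible by 3.  Gaps (`-`) and ambiguous codons are allowed
#'   only in whole-codon units; such codon pairs are excluded from all
#'   counts.
#' @param exons Optional integer vector of exon lengths in *codons*
#'   partitioning the alignment; when given, per-exon rows are returned
#'   in addition to the whole-gene row.
#' @param alpha Significance level passed to [classify_selection()].
#' @return A data.frame with one row per region (`gene`, then `exon<i>`):
#'   codon count, `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `Ka`,
#'   `Ks`, `omega`, `saturated`, `selection_class`.
#' @export
#' @examples
#' ng86_kaks("TTTGCT", "TTCGCT")   # one synonymous difference
ng86_kaks <- function(seq_a, seq_b, exons = NULL, alpha = 0.05) {
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) {
    stop("aligned sequences must have equal codon counts", call. = FALSE)
  }
  tab <- ng86_tables()
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  usable <- !is.na(ia) & !is.na(ib) & tab$aa[ia] != "*" & tab$aa[ib] != "*"

  region_idx <- list(gene = seq_along(ca))
  if (!is.null(exons)) {
    if (sum(exons) != length(ca)) {
      stop("exon codon lengths must partition the alignment", call. = FALSE)
    }
    ends <- cumsum(exons)
    starts <- c(1, head(ends, -1) + 1)
    for (e in seq_along(exons)) {
      region_idx[[paste0("exon", e)]] <- starts[e]:ends[e]
    }
  }

  rows <- lapply(names(region_idx), function(rn) {
    idx <- intersect(region_idx[[rn]], which(usable))
    n_codons <- length(idx)
    if (n_codons == 0) {
      return(data.frame(region = rn, codons = 0L, N_sites = NA_real_,
                        S_sites = NA_real_, Nd = NA_real_, Sd = NA_real_,
                        pN = NA_real_, pS = NA_real_, Ka = NA_real_,
                        Ks = NA_real_, omega = NA_real_, saturated = NA,
                        selection_class = "undefined",
                        stringsAsFactors = FALSE))
    }
    S <- (sum(tab$syn_sites[ia[idx]]) + sum(tab$syn_sites[ib[idx]])) / 2
    N <- 3 * n_codons - S
    lin <- cbind(ia[idx], ib[idx])
    Sd <- sum(tab$Sd[lin])
    Nd <- sum(tab$Nd[lin])
    pS <- if (S > 0) Sd / S else NA_real_
    pN <- if (N > 0) Nd / N else NA_real_
    Ks <- jc_correct(pS)
    Ka <- jc_correct(pN)
    saturated <- isTRUE(pS >= 0.75) || isTRUE(pN >= 0.75)
    if (saturated) {   # uncorrected proportions returned, flagged
      if (is.na(Ks)) Ks <- pS
      if (is.na(Ka)) Ka <- pN
    }
    omega <- if (!is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
    res <- data.frame(region = rn, codons = n_codons, N_sites = N,
                      S_sites = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                      Ka = Ka, Ks = Ks, omega = omega,
                      saturated = saturated,
                      selection_class = NA_character_,
                      stringsAsFactors = FALSE)
    res$selection_class <- classify_selection(res, alpha = alpha)
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the selection regime of a Ka/Ks result
#'
#' `positive` iff omega > 1 and a one-sided exact binomial test of the
#' nonsynonymous share of observed differences against the neutral
#' site-proportion expectation `N/(N+S)` rejects at `alpha`; `purifying`
#' iff omega < 1 with rejection on the other side; otherwise `neutral`;
#' `undefined` when Ks is 0 or unavailable.
#'
#' @param result A one-row data.frame with fields `N_sites`, `S_sites`,
#'   `Nd`, `Sd`, `Ks`, `omega` (as returned by [ng86_kaks()]).
#' @param alpha Significance level (default 0.05).
#' @return One of `"positive"`, `"purifying"`, `"neutral"`, `"undefined"`.
#' @export
classify_selection <- function(result, alpha = 0.05) {
  if (is.na(result$Ks) || result$Ks == 0 || is.na(result$omega)) {
    return("undefined")
  }
  nd <- round(result$Nd)
  total <- round(result$Nd + result$Sd)
  if (total == 0) return("undefined")
  p0 <- result$N_sites / (result$N_sites + result$S_sites)
  if (result$omega > 1) {
    p <- binom.test(nd, total, p = p0, alternative = "greater")$p.value
    if (p < alpha) return("positive")
  } else if (result$omega < 1) {
    p <- binom.test(nd, total, p = p0, alternative = "less")$p.value
    if (p < alpha) return("purifying")
  }
  "neutral"
}

#' Date a duplication event from synonymous divergence
#'
#' Applies the molecular-clock identity `T = Ks / (2 r)`, in years,
#' returned in millions of years.  The synonymous rate `r` is a required
#' parameter of the analysis, not a package default.
#'
#' @param ks Synonymous substitutions per synonymous site (scalar or
#'   vector, e.g. an interval).
#' @param rate Synonymous substitution rate in substitutions/site/year.
#' @return Time(s) since duplication in million years.
#' @export
#' @examples
#' date_duplication(0.35, rate = 3.5e-9)   # 50 My
date_duplication <- function(ks, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("synonymous rate must be a single value > 0", call. = FALSE)
  }
  if (any(ks < 0)) stop("ks must be >= 0", call. = FALSE)
  ks / (2 * rate) / 1e6
}

#' Classify an indel as frameshift or in-frame
#'
#' @param ref_allele,alt_allele Non-empty allele sequences.
#' @return `"frameshift"` iff the length difference is not a multiple of
#'   3, else `"in_frame"`.
#' @export
#' @examples
#' classify_indel("A", "AT")    # +1 bp: frameshift
#' classify_indel("A", "ATTT")  # +3 bp: in frame
classify_indel <- function(ref_allele, alt_allele) {
  if (!nzchar(ref_allele) || !nzchar(alt_allele)) {
    stop("alleles must be non-empty", call. = FALSE)
  }
  if ((nchar(alt_allele) - nchar(ref_allele)) %% 3 != 0) {
    "frameshift"
  } else {
    "in_frame"
  }
}
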