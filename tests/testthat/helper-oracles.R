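# Independent oracles used to validate the package's estimators.
# Deliberately written with different algorithmic structure than the
# implementations they check.

# Exact two-sided p for a 2x2 table with fixed margins by direct
# enumeration of the hypergeometric distribution (point-probability
# two-sided rule), using choose() only.
oracle_fisher_p <- function(m_ref, m_alt, f_ref, f_alt) {
  ref_tot <- m_ref + f_ref
  alt_tot <- m_alt + f_alt
  m_tot <- m_ref + m_alt
  n <- ref_tot + alt_tot
  xs <- max(0, m_tot - alt_tot):min(ref_tot, m_tot)
  probs <- choose(ref_tot, xs) * choose(alt_tot, m_tot - xs) /
    choose(n, m_tot)
  p_obs <- probs[xs == m_ref]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# NG86 per-codon-pair difference counts by recursive pathway
# enumeration (depth-first over remaining differing positions).
oracle_codon_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(cd) unname(code[cd])
  walk <- function(cur, target) {
    dpos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dpos)) {
      return(data.frame(s = 0, n = 0, blocked = FALSE))
    }
    out <- list()
    for (p in dpos) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      step_syn <- translate1(cur) == translate1(nxt) &&
        translate1(cur) != "*"
      blocked_here <- translate1(nxt) == "*" && nxt != target
      rest <- walk(nxt, target)
      rest$s <- rest$s + as.numeric(step_syn)
      rest$n <- rest$n + as.numeric(!step_syn)
      rest$blocked <- rest$blocked | blocked_here
      out[[length(out) + 1]] <- rest
    }
    do.call(rbind, out)
  }
  paths <- walk(c1, c2)
  use <- if (any(!paths$blocked)) !paths$blocked else rep(TRUE, nrow(paths))
  c(sd = mean(paths$s[use]), nd = mean(paths$n[use]))
}

# NG86 synonymous-site fraction of one codon (stop-creating changes
# count as nonsynonymous).
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  if (code[codon] == "*") return(0)
  cd <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), cd[p])) {
      alt <- cd
      alt[p] <- b
      if (code[paste(alt, collapse = "")] == code[codon]) s <- s + 1 / 3
    }
  }
  s
}

# Needleman-Wunsch with affine gaps (gap of length L costs
# open + ext * L), returning the optimal score and the identity of one
# optimal alignment (match-preferring traceback).
oracle_nw <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + sc
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                      Iy[i - 1, j] - open - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                      Ix[i, j - 1] - open - ext)
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback, preferring diagonal moves on ties
  i <- n + 1
  j <- m + 1
  state <- c("M", "Ix", "Iy")[which.max(c(M[n + 1, m + 1],
                                          Ix[n + 1, m + 1],
                                          Iy[n + 1, m + 1]))]
  aln_a <- character(0)
  aln_b <- character(0)
  while (i > 1 || j > 1) {
    if (state == "M") {
      sc <- if (av[i - 1] == bv[j - 1]) match else mismatch
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- c("M", "Ix", "Iy")[which(prev + sc - M[i, j] > -1e-9)[1]]
      aln_a <- c(av[i - 1], aln_a)
      aln_b <- c(bv[j - 1], aln_b)
      i <- i - 1
      j <- j - 1
    } else if (state == "Ix") {
      cand <- c(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                Iy[i - 1, j] - open - ext)
      nxt <- c("M", "Ix", "Iy")[which(cand - Ix[i, j] > -1e-9)[1]]
      aln_a <- c(av[i - 1], aln_a)
      aln_b <- c("-", aln_b)
      i <- i - 1
      state <- nxt
    } else {
      cand <- c(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                Ix[i, j - 1] - open - ext)
      nxt <- c("M", "Iy", "Ix")[which(cand - Iy[i, j] > -1e-9)[1]]
      aln_a <- c("-", aln_a)
      aln_b <- c(bv[j - 1], aln_b)
      j <- j - 1
      state <- nxt
    }
  }
  gap <- aln_a == "-" | aln_b == "-"
  core <- which(!gap)
  keep <- seq(min(core), max(core))
  list(score = score,
       identity = round(100 * sum(aln_a[keep] == aln_b[keep]) /
                          length(keep), 2))
}

random_codon_seq <- function(n_codons) {
  codons <- sdrscan:::codon_universe()
  sense <- codons[Biostrings::GENETIC_CODE[codons] != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
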