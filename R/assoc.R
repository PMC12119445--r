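#' Two-sided Fisher exact p for a sex x allele 2x2 table
#'
#' Two-sided by the point-probability method (all tables with fixed
#' margins whose hypergeometric probability does not exceed the
#' observed table's are summed), as implemented in [stats::fisher.test].
#'
#' @param m_ref,m_alt,f_ref,f_alt REF/ALT allele counts in males and
#'   females.
#' @return p-value in (0, 1].
#' @export
sex_table_test <- function(m_ref, m_alt, f_ref, f_alt) {
  fisher.test(matrix(c(m_ref, m_alt, f_ref, f_alt), nrow = 2,
                     byrow = TRUE))$p.value
}

#' Hudson's per-site Fst components for two groups
#'
#' Numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the per-site estimate is their
#' ratio.  Windowed values should combine sites as ratio-of-sums
#' (see [window_fst()]).
#'
#' @param p1,p2 ALT allele frequencies in the two groups.
#' @param n1,n2 Allele (chromosome) sample sizes; must be >= 2.
#' @return data.frame with `num`, `den`, `fst_raw` (num/den, `NaN` when
#'   both groups are monomorphic for the same allele) and `fst` clipped
#'   to \[0, 1\].
#' @export
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  raw <- ifelse(den > 0, num / den, ifelse(num == 0, 0, NaN))
  data.frame(num = num, den = den, fst_raw = raw,
             fst = pmin(1, pmax(0, raw)))
}

#' Per-site sex association and Fst over a genotype matrix
#'
#' For every site with at least one non-missing genotype in each sex,
#' builds the sex x allele 2x2 count table, computes the two-sided
#' Fisher exact p (distinct tables are computed once and reused),
#' `-log10(p)`, and Hudson's per-site Fst.  Monomorphic sites get
#' `p = 1`, `fst = 0` and a flag.  Sites missing a whole sex (e.g.
#' Y-specific hemizygous sites, where all females are `./.`) are
#' excluded and tallied in the `skipped` attribute.
#'
#' @param geno Sites x individuals ALT-dosage matrix (0/1/2, `NA`
#'   missing).
#' @param sexes Character vector (`"M"`/`"F"`) per individual.
#' @param sites Optional data.frame with `contig` and `pos` carried
#'   through to the output.
#' @return data.frame (one row per tested site): allele counts,
#'   `p_value`, `neg_log_p`, `fst`, `fst_raw`, `fst_num`, `fst_den`,
#'   `monomorphic`; attribute `skipped` counts excluded sites.
#' @export
snp_sex_association <- function(geno, sexes, sites = NULL) {
  stopifnot(ncol(geno) == length(sexes), all(sexes %in% c("M", "F")))
  gm <- geno[, sexes == "M", drop = FALSE]
  gf <- geno[, sexes == "F", drop = FALSE]
  m_n <- 2L * rowSums(!is.na(gm))
  f_n <- 2L * rowSums(!is.na(gf))
  keep <- m_n > 0 & f_n > 0
  skipped <- sum(!keep)

  m_alt <- rowSums(gm, na.rm = TRUE)[keep]
  f_alt <- rowSums(gf, na.rm = TRUE)[keep]
  m_n <- m_n[keep]
  f_n <- f_n[keep]
  m_ref <- m_n - m_alt
  f_ref <- f_n - f_alt

  key <- paste(m_ref, m_alt, f_ref, f_alt, sep = ":")
  uk <- !duplicated(key)
  up <- mapply(sex_table_test, m_ref[uk], m_alt[uk], f_ref[uk], f_alt[uk])
  p <- unname(up[match(key, key[uk])])

  mono <- (m_alt + f_alt == 0) | (m_ref + f_ref == 0)
  p[mono] <- 1
  fst <- hudson_fst(m_alt / m_n, f_alt / f_n, m_n, f_n)
  fst$fst[mono] <- 0
  fst$fst_raw[mono] <- 0

  out <- data.frame(m_ref = m_ref, m_alt = m_alt, f_ref = f_ref,
                    f_alt = f_alt, p_value = p,
                    neg_log_p = -log10(p), fst = fst$fst,
                    fst_raw = fst$fst_raw, fst_num = fst$num,
                    fst_den = fst$den, monomorphic = mono)
  if (!is.null(sites)) {
    out <- cbind(sites[keep, c("contig", "pos"), drop = FALSE], out)
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

#' Sex association of a presence/absence marker
#'
#' Tests whether a marker (e.g. a candidate Y-borne gene amplified
#' across a panel) is associated with sex, and flags perfect
#' male-presence / female-absence separation.
#'
#' @param presence Logical vector, one entry per individual.
#' @param sexes Character vector (`"M"`/`"F"`) per individual.
#' @return list: `table` (2x2 sex x presence), `p_value` (two-sided
#'   Fisher exact), `perfect_separation` (`TRUE` iff presence <=> male).
#' @export
#' @examples
#' marker_presence_association(rep(c(TRUE, FALSE), each = 8),
#'                             rep(c("M", "F"), each = 8))
marker_presence_association <- function(presence, sexes) {
  stopifnot(length(presence) == length(sexes),
            all(sexes %in% c("M", "F")), any(sexes == "M"),
            any(sexes == "F"))
  tab <- table(factor(sexes, c("M", "F")),
               factor(presence, c(TRUE, FALSE),
                      labels = c("present", "absent")))
  p <- fisher.test(tab)$p.value
  perfect <- all(presence[sexes == "M"]) && !any(presence[sexes == "F"])
  list(table = tab, p_value = p, perfect_separation = perfect)
}
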