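#' Windowed Fst as ratio of sums
#'
#' Combines per-site Hudson components within each window as
#' `sum(numerators) / sum(denominators)` (the ratio-of-sums estimator,
#' robust at low per-site information).  Windows without SNPs get `NA`.
#'
#' @param assoc Per-site table from [snp_sex_association()] (needs
#'   `pos`, `fst_num`, `fst_den`).
#' @param windows data.frame from [make_windows()].
#' @return Numeric vector of per-window Fst (clipped to \[0, 1\];
#'   `fst_raw` attribute keeps the unclipped values).
#' @export
window_fst <- function(assoc, windows) {
  raw <- vapply(seq_len(nrow(windows)), function(i) {
    j <- assoc$pos >= windows$start[i] & assoc$pos < windows$end[i]
    if (!any(j)) return(NA_real_)
    den <- sum(assoc$fst_den[j])
    if (den == 0) return(0)
    sum(assoc$fst_num[j]) / den
  }, numeric(1))
  out <- pmin(1, pmax(0, raw))
  attr(out, "fst_raw") <- raw
  out
}

#' Per-window per-sex mean normalized coverage
#'
#' Bin-length-weighted mean of normalized depth over the bins
#' overlapping each window, averaged over the individuals of each sex.
#' Windows with no depth bins get `NA`.
#'
#' @param profile A `depth_profile` from [normalize_depth()].
#' @param windows data.frame from [make_windows()].
#' @param contig Contig the windows refer to.
#' @return data.frame: `cov_male`, `cov_female`.
#' @export
window_coverage <- function(profile, windows, contig) {
  bins <- profile$bins
  bi <- which(bins$contig == contig)
  is_male <- profile$individuals$sex == "M"
  mean_m <- rowMeans(profile$norm[bi, is_male, drop = FALSE])
  mean_f <- rowMeans(profile$norm[bi, !is_male, drop = FALSE])
  br <- IRanges::IRanges(bins$start[bi] + 1, bins$end[bi])
  wr <- IRanges::IRanges(windows$start + 1, windows$end)
  ov <- IRanges::findOverlaps(wr, br)
  qh <- S4Vectors::queryHits(ov)
  w <- IRanges::width(IRanges::pintersect(
    wr[qh], br[S4Vectors::subjectHits(ov)]))
  cm <- rep(NA_real_, nrow(windows))
  cf <- rep(NA_real_, nrow(windows))
  if (length(qh)) {
    sh <- S4Vectors::subjectHits(ov)
    idx <- sort(unique(qh))
    wsum <- rowsum(w, qh)
    cm[idx] <- rowsum(w * mean_m[sh], qh) / wsum
    cf[idx] <- rowsum(w * mean_f[sh], qh) / wsum
  }
  data.frame(cov_male = cm, cov_female = cf)
}

#' Per-window X-Y nucleotide distance
#'
#' p-distance (`mismatches / aligned non-gap sites`) between X and Y
#' homologous sequence per window on the Y coordinate, using an
#' alignment map of co-linear segments.  Optionally Jukes-Cantor
#' corrected when `p < 0.75` (saturated windows keep the p-distance and
#' are flagged).  Windows with fewer than `min_aligned_sites` aligned
#' positions get `NA`.
#'
#' @param x_seq,y_seq Character sequences of the X and Y contigs.
#' @param alignment_map data.frame with `x_start`, `x_end`, `y_start`,
#'   `y_end` (0-based half-open, `+` strand co-linear segments).
#' @param windows data.frame from [make_windows()] on the Y coordinate.
#' @param jc Apply Jukes-Cantor correction.
#' @param min_aligned_sites Minimum aligned sites per window.
#' @return data.frame: `dxy`, `aligned_sites`, `mismatches`,
#'   `saturated`.
#' @export
window_dxy <- function(x_seq, y_seq, alignment_map, windows, jc = FALSE,
                       min_aligned_sites = 100) {
  ylen <- nchar(y_seq)
  aligned <- logical(ylen)
  mism <- logical(ylen)
  xc <- strsplit(x_seq, "", fixed = TRUE)[[1]]
  yc <- strsplit(y_seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(alignment_map))) {
    ys <- alignment_map$y_start[i]
    ye <- alignment_map$y_end[i]
    xs <- alignment_map$x_start[i]
    if (ye - ys != alignment_map$x_end[i] - xs) {
      stop("alignment map segment lengths differ", call. = FALSE)
    }
    ypos <- (ys + 1L):ye
    xpos <- (xs + 1L):(xs + (ye - ys))
    aligned[ypos] <- TRUE
    mism[ypos] <- yc[ypos] != xc[xpos]
  }
  ca <- cumsum(aligned)
  cm <- cumsum(mism)
  range_sum <- function(cs, s, e) cs[e] - if (s > 0) cs[s] else 0
  n_aln <- mapply(range_sum, list(ca), windows$start, windows$end)
  n_mis <- mapply(range_sum, list(cm), windows$start, windows$end)
  p <- ifelse(n_aln >= min_aligned_sites, n_mis / n_aln, NA_real_)
  saturated <- !is.na(p) & p >= 0.75
  d <- p
  if (jc) d <- ifelse(saturated, p, jc_correct(p))
  data.frame(dxy = d, aligned_sites = n_aln, mismatches = n_mis,
             saturated = saturated)
}

#' Assemble per-window scan statistics for one contig
#'
#' Combines sex-association, Fst, per-sex coverage and (optionally)
#' X-Y divergence into one `WindowStat` table, the per-window evidence
#' [call_sdr()] consumes.
#'
#' @param windows data.frame from [make_windows()].
#' @param assoc Per-site association table for this contig (from
#'   [snp_sex_association()], with `pos`).
#' @param profile Optional `depth_profile` for coverage columns.
#' @param contig Contig name (needed with `profile`).
#' @param dxy Optional data.frame from [window_dxy()] (row-aligned with
#'   `windows`).
#' @param y_specific_pos Optional positions of sites excluded as
#'   Y-specific, tallied per window.
#' @param neg_log_p_min Threshold defining a "sex-associated" SNP for
#'   the per-window `n_assoc` tally (default 2, i.e. p < 0.01).
#' @return data.frame: window coords plus `n_snps`, `n_assoc`,
#'   `max_neg_log_p`, `mean_fst`, `cov_male`, `cov_female`, `dxy`,
#'   `n_y_specific`.
#' @export
window_stats <- function(windows, assoc, profile = NULL, contig = NULL,
                         dxy = NULL, y_specific_pos = NULL,
                         neg_log_p_min = 2) {
  n <- nrow(windows)
  stat <- data.frame(start = windows$start, end = windows$end,
                     n_snps = integer(n), n_assoc = integer(n),
                     max_neg_log_p = rep(NA_real_, n),
                     mean_fst = rep(NA_real_, n),
                     cov_male = rep(NA_real_, n),
                     cov_female = rep(NA_real_, n),
                     dxy = rep(NA_real_, n),
                     n_y_specific = integer(n))
  for (i in seq_len(n)) {
    j <- assoc$pos >= windows$start[i] & assoc$pos < windows$end[i]
    stat$n_snps[i] <- sum(j)
    if (any(j)) {
      stat$n_assoc[i] <- sum(assoc$neg_log_p[j] > neg_log_p_min)
      stat$max_neg_log_p[i] <- max(assoc$neg_log_p[j])
    }
    if (!is.null(y_specific_pos)) {
      stat$n_y_specific[i] <- sum(y_specific_pos >= windows$start[i] &
                                    y_specific_pos < windows$end[i])
    }
  }
  stat$mean_fst <- as.numeric(window_fst(assoc, windows))
  if (!is.null(profile)) {
    cov <- window_coverage(profile, windows, contig)
    stat$cov_male <- cov$cov_male
    stat$cov_female <- cov$cov_female
  }
  if (!is.null(dxy)) stat$dxy <- dxy$dxy
  stat
}

#' SDR calling rules
#'
#' A window qualifies as SDR evidence if any of:
#'
#' * association: `max_neg_log_p > neg_log_p_min` AND the fraction of
#'   tested SNPs beyond that threshold is at least `assoc_frac_min`
#'   (sex-associated SNPs must be *enriched*, not merely present — a
#'   lone sub-0.01 p among hundreds of SNPs is expected by chance);
#' * female absence: female coverage < `female_absent_max` with male
#'   coverage in the half-depth band (Y-specific sequence);
#' * divergence: `dxy > dxy_min`.
#'
#' @param neg_log_p_min -log10(p) threshold (default 2).
#' @param assoc_frac_min Minimum fraction of tested SNPs in a window
#'   exceeding `neg_log_p_min` (default 0.1).
#' @param female_absent_max,male_cov_low,male_cov_high Coverage rule
#'   thresholds (defaults match [classifier_config()]).
#' @param dxy_min Divergence threshold, exclusive (default 0).
#' @param gap_windows Merge qualifying windows separated by at most
#'   this many non-qualifying windows (default 1).
#' @return List of class `sdr_rules`.
#' @export
sdr_rules <- function(neg_log_p_min = 2, assoc_frac_min = 0.1,
                      female_absent_max = 0.1, male_cov_low = 0.3,
                      male_cov_high = 0.7, dxy_min = 0, gap_windows = 1) {
  structure(list(neg_log_p_min = neg_log_p_min,
                 assoc_frac_min = assoc_frac_min,
                 female_absent_max = female_absent_max,
                 male_cov_low = male_cov_low,
                 male_cov_high = male_cov_high,
                 dxy_min = dxy_min, gap_windows = gap_windows),
            class = "sdr_rules")
}

#' Call sex-determining region intervals from window statistics
#'
#' Flags qualifying windows under [sdr_rules()], merges runs of
#' qualifying windows with the configured gap tolerance into maximal
#' intervals, and ranks the intervals by summed evidence (number of
#' criteria fired over their windows).
#'
#' @param stats `WindowStat` table from [window_stats()] for a single
#'   candidate sex contig.
#' @param rules An [sdr_rules()].
#' @return List of class `sdr_call`: `intervals` (data.frame start,
#'   end, n_windows, evidence; zero rows when nothing qualifies),
#'   `window_flags` (per-window logicals per criterion), `n_y_specific`
#'   (total Y-specific site tally over called intervals).
#' @export
call_sdr <- function(stats, rules = sdr_rules()) {
  frac <- ifelse(stats$n_snps > 0, stats$n_assoc / stats$n_snps, 0)
  q_assoc <- !is.na(stats$max_neg_log_p) &
    stats$max_neg_log_p > rules$neg_log_p_min &
    frac >= rules$assoc_frac_min
  q_cov <- !is.na(stats$cov_female) & !is.na(stats$cov_male) &
    stats$cov_female < rules$female_absent_max &
    stats$cov_male >= rules$male_cov_low &
    stats$cov_male <= rules$male_cov_high
  q_dxy <- !is.na(stats$dxy) & stats$dxy > rules$dxy_min
  qualifies <- q_assoc | q_cov | q_dxy
  flags <- data.frame(start = stats$start, end = stats$end,
                      assoc = q_assoc, coverage = q_cov, dxy = q_dxy,
                      qualifies = qualifies)
  q <- which(qualifies)
  if (!length(q)) {
    return(structure(list(
      intervals = data.frame(start = numeric(0), end = numeric(0),
                             n_windows = integer(0),
                             evidence = numeric(0)),
      window_flags = flags, n_y_specific = 0L), class = "sdr_call"))
  }
  runs <- cumsum(c(1, diff(q) > rules$gap_windows + 1))
  iv <- do.call(rbind, lapply(split(q, runs), function(idx) {
    data.frame(start = min(stats$start[idx]), end = max(stats$end[idx]),
               n_windows = length(idx),
               evidence = sum(q_assoc[idx] + q_cov[idx] + q_dxy[idx]))
  }))
  iv <- iv[order(-iv$evidence), , drop = FALSE]
  rownames(iv) <- NULL
  nys <- sum(vapply(seq_len(nrow(iv)), function(i) {
    sum(stats$n_y_specific[stats$start >= iv$start[i] &
                             stats$end <= iv$end[i]])
  }, numeric(1)))
  structure(list(intervals = iv, window_flags = flags,
                 n_y_specific = nys), class = "sdr_call")
}

#' @exportS3Method base::print
print.sdr_call <- function(x, ...) {
  if (!nrow(x$intervals)) {
    cat("sdr_call: scanned, none found\n")
  } else {
    cat("sdr_call:", nrow(x$intervals), "interval(s)\n")
    print(x$intervals)
  }
  invisible(x)
}

#' Jaccard overlap between an SDR call and a truth interval
#'
#' @param call An `sdr_call` (the top-ranked interval is used) or a
#'   two-element numeric `c(start, end)`.
#' @param truth Two-element numeric `c(start, end)`.
#' @return Intersection-over-union in \[0, 1\]; 0 for an empty call.
#' @export
sdr_jaccard <- function(call, truth) {
  if (inherits(call, "sdr_call")) {
    if (!nrow(call$intervals)) return(0)
    call <- c(call$intervals$start[1], call$intervals$end[1])
  }
  inter <- max(0, min(call[2], truth[2]) - max(call[1], truth[1]))
  union <- (call[2] - call[1]) + (truth[2] - truth[1]) - inter
  if (union <= 0) return(0)
  inter / union
}
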