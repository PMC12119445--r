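#' Normalize per-bin read depth by each individual's genome-wide median
#'
#' "Overall genomic depth" for an individual is taken as the genome-wide
#' median of that individual's per-bin raw depths (robust to sex-linked
#' outlier bins).  Each depth is divided by it, so scaling all of one
#' individual's depths by any constant c > 0 leaves the profile
#' unchanged.
#'
#' @param samples A `sample_set`, or a list with elements `depth_bins`
#'   (data.frame contig/start/end), `depth` (bins x individuals matrix)
#'   and `individuals` (data.frame id/sex).
#' @return A list of class `depth_profile`: `bins`, `norm` (normalized
#'   matrix), `individuals`, `medians`.
#' @export
normalize_depth <- function(samples) {
  bins <- samples$depth_bins
  depth <- samples$depth
  ind <- samples$individuals
  stopifnot(nrow(depth) == nrow(bins), ncol(depth) == nrow(ind))
  med <- apply(depth, 2, median)
  zero <- med <= 0
  if (any(zero)) {
    stop("zero median depth for individual(s): ",
         paste(ind$id[zero], collapse = ", "), call. = FALSE)
  }
  norm <- sweep(depth, 2, med, "/")
  colnames(norm) <- ind$id
  structure(list(bins = bins, norm = norm, individuals = ind,
                 medians = med), class = "depth_profile")
}

#' Linkage-classifier thresholds
#'
#' @param half_depth_low,half_depth_high Bounds of the half-depth band a
#'   sex-linked contig's male depth ratio must fall in (defaults 0.3 and
#'   0.7, i.e. ~0.3-0.7x the overall genomic depth).
#' @param female_absent_max Maximum female depth ratio for a contig to
#'   count as absent from females (default 0.1).
#' @param min_contig_len Contigs shorter than this are not classified.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(half_depth_low = 0.3, half_depth_high = 0.7,
                              female_absent_max = 0.1, min_contig_len = 0) {
  stopifnot(half_depth_low > 0, half_depth_low < half_depth_high,
            female_absent_max < half_depth_low, min_contig_len >= 0)
  structure(list(half_depth_low = half_depth_low,
                 half_depth_high = half_depth_high,
                 female_absent_max = female_absent_max,
                 min_contig_len = min_contig_len),
            class = "classifier_config")
}

#' Per-contig per-sex mean normalized depth
#'
#' Bin-length-weighted mean of normalized depth per contig, averaged
#' over the individuals of each sex.
#'
#' @param profile A `depth_profile` from [normalize_depth()].
#' @return data.frame: contig, male_ratio, female_ratio.
#' @export
contig_depth_ratios <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  bins <- profile$bins
  wlen <- bins$end - bins$start
  is_male <- profile$individuals$sex == "M"
  per_ind_mean <- function(cols) {
    # bin-length-weighted contig mean per individual, then sex average
    sapply(unique(bins$contig), function(ctg) {
      i <- bins$contig == ctg
      mean(colSums(profile$norm[i, cols, drop = FALSE] * wlen[i]) /
             sum(wlen[i]))
    })
  }
  data.frame(contig = unique(bins$contig),
             male_ratio = per_ind_mean(which(is_male)),
             female_ratio = per_ind_mean(which(!is_male)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify contigs as autosomal, X-linked or Y-linked
#'
#' Depth-ratio rules, with male-specific marker hits as corroborating
#' Y evidence:
#'
#' * `Y_linked`: male ratio in the half-depth band \[low, high\] AND
#'   (female ratio <= `female_absent_max` OR marker hits > 0);
#' * `X_linked`: male ratio in the half-depth band, female ratio in
#'   (`female_absent_max`, 1 + (1 - high)\], no marker hits;
#' * `autosomal`: both sex ratios within \[high, 2 - high\] around 1;
#' * otherwise `ambiguous` (never dropped).
#'
#' The call is a pure, order-independent function of the per-contig
#' evidence and the thresholds.
#'
#' @param profile A `depth_profile` from [normalize_depth()].
#' @param marker_hits Optional named integer vector of male-specific
#'   marker hit counts per contig (missing contigs count 0).
#' @param cfg A [classifier_config()].
#' @param contig_lengths Optional named lengths used with
#'   `min_contig_len`.
#' @return data.frame: contig, class, male_ratio, female_ratio, markers.
#' @export
classify_contigs <- function(profile, marker_hits = NULL,
                             cfg = classifier_config(),
                             contig_lengths = NULL) {
  ratios <- contig_depth_ratios(profile)
  hits <- integer(nrow(ratios))
  if (!is.null(marker_hits)) {
    m <- marker_hits[ratios$contig]
    hits <- ifelse(is.na(m), 0L, as.integer(m))
  }
  lo <- cfg$half_depth_low
  hi <- cfg$half_depth_high
  fa <- cfg$female_absent_max
  cls <- vapply(seq_len(nrow(ratios)), function(i) {
    m <- ratios$male_ratio[i]
    f <- ratios$female_ratio[i]
    half <- m >= lo && m <= hi
    if (half && (f <= fa || hits[i] > 0)) return("Y_linked")
    if (half && f > fa && f <= 1 + (1 - hi) && hits[i] == 0) {
      return("X_linked")
    }
    if (m >= hi && m <= 2 - hi && f >= hi && f <= 2 - hi) {
      return("autosomal")
    }
    "ambiguous"
  }, character(1))
  out <- data.frame(contig = ratios$contig, class = cls,
                    male_ratio = ratios$male_ratio,
                    female_ratio = ratios$female_ratio,
                    markers = hits, stringsAsFactors = FALSE)
  if (!is.null(contig_lengths) && cfg$min_contig_len > 0) {
    keep <- contig_lengths[out$contig] >= cfg$min_contig_len
    out <- out[is.na(keep) | keep, , drop = FALSE]
  }
  out
}
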