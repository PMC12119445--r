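#' Per-window repeat-class density
#'
#' Merges overlapping intervals of the same class, then reports, for
#' every window, `masked bp / window bp` per repeat class.  Because
#' different classes can overlap, class densities within a window may
#' sum above 1; such windows are flagged in the `class_overlap`
#' attribute.
#'
#' @param track data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and `class`.
#' @param windows data.frame from [make_windows()].
#' @param contig Contig the windows refer to.
#' @param classes Classes to report (default: those present).
#' @return data.frame: `start`, `end`, one density column per class.
#' @export
#' @examples
#' track <- data.frame(contig = "c", start = 0, end = 25000,
#'                     class = "LINE")
#' repeat_density(track, make_windows(50000, 50000, 50000), "c")
repeat_density <- function(track, windows, contig,
                           classes = sort(unique(track$class))) {
  out <- data.frame(start = windows$start, end = windows$end)
  wr <- IRanges::IRanges(windows$start + 1, windows$end)
  wlen <- windows$end - windows$start
  for (cl in classes) {
    sel <- track$contig == contig & track$class == cl
    merged <- IRanges::reduce(IRanges::IRanges(track$start[sel] + 1,
                                               track$end[sel]))
    ov <- IRanges::findOverlaps(wr, merged)
    covered <- numeric(nrow(windows))
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        wr[S4Vectors::queryHits(ov)], merged[S4Vectors::subjectHits(ov)]))
      agg <- rowsum(w, S4Vectors::queryHits(ov))
      covered[as.integer(rownames(agg))] <- agg
    }
    out[[cl]] <- covered / wlen
  }
  dens <- as.matrix(out[, classes, drop = FALSE])
  attr(out, "class_overlap") <- rowSums(dens) > 1
  out
}

#' Repeat-class enrichment between two regions
#'
#' Compares the merged masked fraction of one repeat class between two
#' disjoint regions (e.g. the flank of a candidate sex-determining gene
#' vs the corresponding flank of its autosomal parent).  Reports the
#' density fold change, a Fisher exact p on the 2x2 masked/unmasked bp
#' table (with a caveat flag: base pairs are autocorrelated, so this p
#' overstates certainty), and a seeded block-permutation p (regions
#' tiled into blocks whose labels are shuffled).
#'
#' @param track Repeat track data.frame (`contig`, `start`, `end`,
#'   `class`).
#' @param region_a,region_b Lists/data.frames with `contig`, `start`,
#'   `end` (0-based half-open); must be non-empty and disjoint when on
#'   one contig.
#' @param class Repeat class to test (e.g. `"LINE"`).
#' @param block_size Permutation block width in bp (default 10 kbp).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return List of class `enrichment_result`: densities, masked/total
#'   bp, `fold`, `p_fisher`, `fisher_caveat = TRUE`, `p_perm`.
#' @export
region_enrichment <- function(track, region_a, region_b, class,
                              block_size = 1e4, n_perm = 1000,
                              seed = 1L) {
  for (r in list(region_a, region_b)) {
    if (r$end - r$start <= 0) stop("zero-length region", call. = FALSE)
  }
  if (region_a$contig == region_b$contig &&
      max(region_a$start, region_b$start) <
        min(region_a$end, region_b$end)) {
    stop("regions must be disjoint", call. = FALSE)
  }
  blocks_of <- function(region) {
    st <- seq(region$start, region$end - 1, by = block_size)
    data.frame(contig = region$contig, start = st,
               end = pmin(st + block_size, region$end))
  }
  masked_bp <- function(region) {
    sel <- track$contig == region$contig & track$class == class
    merged <- IRanges::reduce(IRanges::IRanges(track$start[sel] + 1,
                                               track$end[sel]))
    sum(IRanges::width(IRanges::restrict(merged, region$start + 1,
                                         region$end)))
  }
  tot_a <- region_a$end - region_a$start
  tot_b <- region_b$end - region_b$start
  m_a <- masked_bp(region_a)
  m_b <- masked_bp(region_b)
  d_a <- m_a / tot_a
  d_b <- m_b / tot_b
  fold <- if (d_b > 0) d_a / d_b else Inf
  p_fisher <- fisher.test(matrix(round(c(m_a, tot_a - m_a,
                                         m_b, tot_b - m_b)), 2))$p.value

  ba <- blocks_of(region_a)
  bb <- blocks_of(region_b)
  blocks <- rbind(ba, bb)
  lab <- rep(c(TRUE, FALSE), c(nrow(ba), nrow(bb)))
  bm <- vapply(seq_len(nrow(blocks)), function(i)
    masked_bp(blocks[i, ]), numeric(1))
  blen <- blocks$end - blocks$start
  dens_diff <- function(l) sum(bm[l]) / sum(blen[l]) -
    sum(bm[!l]) / sum(blen[!l])
  obs <- dens_diff(lab)
  set.seed(stage_seed(seed, "repeats"))
  exceed <- vapply(seq_len(n_perm), function(i)
    abs(dens_diff(sample(lab))) >= abs(obs), logical(1))
  p_perm <- (1 + sum(exceed)) / (n_perm + 1)

  structure(list(class = class, density_a = d_a, density_b = d_b,
                 masked_a = m_a, masked_b = m_b, total_a = tot_a,
                 total_b = tot_b, fold = fold, p_fisher = p_fisher,
                 fisher_caveat = TRUE, p_perm = p_perm,
                 n_perm = n_perm), class = "enrichment_result")
}

#' @exportS3Method base::print
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s enrichment: %.4f vs %.4f (fold %.2f)\n",
              x$class, x$density_a, x$density_b, x$fold))
  cat(sprintf("  permutation p = %.4g (%d perms); Fisher bp-table p = %.3g",
              x$p_perm, x$n_perm, x$p_fisher),
      "[caveat: bp are autocorrelated]\n")
  invisible(x)
}

#' Read a RepeatMasker .out annotation
#'
#' Whitespace-delimited dialect with the standard 3-line header; the
#' repeat class is the class/family column's prefix before `/`.
#' Coordinates are converted to 0-based half-open.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return data.frame: `contig`, `start`, `end`, `class`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  data.frame(
    contig = vapply(fields, `[`, character(1), 5),
    start = as.numeric(vapply(fields, `[`, character(1), 6)) - 1,
    end = as.numeric(vapply(fields, `[`, character(1), 7)),
    class = sub("/.*$", "", vapply(fields, `[`, character(1), 11)),
    stringsAsFactors = FALSE
  )
}
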