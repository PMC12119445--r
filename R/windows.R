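#' Sliding windows over a contig
#'
#' Tiles `[0, contig_length)` with half-open windows of width `w` at step
#' `s`.  The final window is truncated at the contig end and never
#' extends past it; no window is started beyond the point where the
#' previous window already reaches the end.
#'
#' @param contig_length Contig length (bp).
#' @param w Window width (bp), default 50 kbp.
#' @param s Step (bp), default 25 kbp; requires `0 < s <= w <=
#'   contig_length`.
#' @return data.frame with columns `start`, `end` (0-based half-open).
#' @export
#' @examples
#' make_windows(100000, 50000, 25000)
make_windows <- function(contig_length, w = 50000, s = 25000) {
  if (!(s > 0 && s <= w)) {
    stop("window parameters require 0 < step <= width", call. = FALSE)
  }
  if (w > contig_length) {
    stop("window width exceeds contig length", call. = FALSE)
  }
  k <- 0
  while (s * k + w < contig_length) k <- k + 1
  starts <- s * (0:k)      # the final window is truncated at the end
  data.frame(start = starts, end = pmin(starts + w, contig_length))
}
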