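# Per-base depth-of-coverage summaries: fraction of bases at 0x and at or
# above a threshold, combined totals, and windowed depth profiles.
#
# Depth input is a 3-column table (chrom, pos, depth); positions absent from
# the table have depth 0 over the declared chromosome length, matching
# common depth-tool output without requiring alignments. "Combined coverage"
# is the per-base sum of depth across samples, supplied pre-summed.

#' Summarize per-base depth
#'
#' @param depths either a non-negative numeric vector of per-base depths, or
#'   a data frame with columns `chrom`, `pos`, `depth` (absent positions
#'   count as depth 0).
#' @param chrom_lengths named vector of chromosome lengths; required with
#'   the data-frame input to define the denominator.
#' @param threshold the high-coverage cutoff (default 30); a base with depth
#'   exactly `threshold` counts toward the `>=` bucket.
#' @return list with `pct_zero`, `pct_ge_threshold`, `combined_total`.
#' @export
depth_summary <- function(depths, chrom_lengths = NULL, threshold = 30) {
  if (is.data.frame(depths)) {
    if (is.null(chrom_lengths))
      stop("chrom_lengths required with tabular depth input")
    n_bases <- sum(chrom_lengths)
    d <- depths$depth
    if (any(d < 0)) stop("depths must be non-negative")
    n_zero <- n_bases - sum(d > 0)
    n_ge <- sum(d >= threshold)
    total <- sum(d)
  } else {
    if (length(depths) == 0) stop("empty depth input")
    if (any(depths < 0)) stop("depths must be non-negative")
    n_bases <- length(depths)
    n_zero <- sum(depths == 0)
    n_ge <- sum(depths >= threshold)
    total <- sum(depths)
  }
  if (n_bases == 0) stop("empty depth input")
  list(pct_zero = 100 * n_zero / n_bases,
       pct_ge_threshold = 100 * n_ge / n_bases,
       combined_total = total)
}

#' Windowed depth profile
#'
#' Per-window sum of depth over the bases inside the window (bases without a
#' table entry contribute 0).
#'
#' @param depths data frame with columns `chrom`, `pos`, `depth`, sorted by
#'   position within chromosome.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin,step window size and step in bp (defaults 100 kb / 50 kb).
#' @return a `window_stat` data frame of summed coverage.
#' @export
windowed_depth <- function(depths, chrom_lengths, bin = 1e5, step = 5e4) {
  w <- windows_for_chroms(chrom_lengths, bin, step)
  aggregate_windows(depths$chrom, depths$pos, depths$depth, w,
                    stat = "sum", min_values = 0)
}
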