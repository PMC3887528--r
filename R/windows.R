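# Generic sliding-window engine shared by the coverage, diversity, F_ST and
# LD analyses. Windows are 0-based half-open internally; site positions are
# 1-based (VCF convention), so a window [start, end) contains a site at
# 1-based position p iff start < p <= end.

#' Build sliding windows over a chromosome
#'
#' Windows are anchored at coordinate 0, advance by `step`, and the terminal
#' window is truncated at `chrom_length` so that every base is covered at
#' least once. Coordinates are 0-based half-open.
#'
#' @param chrom_length chromosome length in bp.
#' @param bin window size in bp.
#' @param step step between window starts in bp; defaults to `bin`
#'   (non-overlapping tiling).
#' @return data frame with columns `start`, `end`.
#' @examples
#' make_windows(250000, 100000, 50000)
#' @export
make_windows <- function(chrom_length, bin, step = bin) {
  if (length(chrom_length) != 1 || is.na(chrom_length) || chrom_length <= 0)
    stop("chrom_length must be a positive scalar")
  if (bin <= 0 || step <= 0) stop("bin and step must be positive")
  if (step > bin) stop("step must not exceed bin")
  n_extra <- max(0, ceiling((chrom_length - bin) / step))
  starts <- seq(0, by = step, length.out = n_extra + 1)
  data.frame(start = starts, end = pmin(starts + bin, chrom_length))
}

#' Aggregate positioned values into sliding windows
#'
#' Each value contributes to every window overlapping its position (windows
#' may overlap when `step < bin`). Windows with fewer than `min_values`
#' contributing values are flagged excluded and their value reported as `NA`,
#' following the figure-caption convention of dropping thin windows.
#'
#' @param chrom,pos,value parallel vectors: chromosome, 1-based position, and
#'   the per-site value. Positions must be sorted within each chromosome.
#' @param windows data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [make_windows()] applied per chromosome.
#' @param stat `"mean"` or `"sum"`.
#' @param min_values minimum number of contributing values for a window to be
#'   retained; default 0 (keep all).
#' @return a `window_stat` data frame: `chrom`, `start`, `end`, `n_values`,
#'   `value`, `excluded`.
#' @export
aggregate_windows <- function(chrom, pos, value, windows,
                              stat = c("mean", "sum"), min_values = 0) {
  stat <- match.arg(stat)
  stopifnot(length(chrom) == length(pos), length(pos) == length(value))
  out <- windows[, c("chrom", "start", "end")]
  out$n_values <- 0L
  out$value <- NA_real_
  for (ch in unique(out$chrom)) {
    sel <- chrom == ch
    p <- pos[sel]
    v <- value[sel]
    if (is.unsorted(p)) stop("positions must be sorted within chromosome ", ch)
    wsel <- which(out$chrom == ch)
    cs <- c(0, cumsum(v))
    # window [start, end) holds 1-based positions p with start < p <= end
    lo <- findInterval(out$start[wsel] + 0.5, p)
    hi <- findInterval(out$end[wsel] + 0.5, p)
    n <- hi - lo
    s <- cs[hi + 1] - cs[lo + 1]
    out$n_values[wsel] <- n
    out$value[wsel] <- switch(stat,
      sum = s,
      mean = ifelse(n > 0, s / n, NA_real_))
  }
  out$excluded <- out$n_values < min_values
  out$value[out$excluded] <- NA_real_
  class(out) <- c("window_stat", "data.frame")
  out
}

# Per-chromosome window table from a named vector of chromosome lengths.
windows_for_chroms <- function(chrom_lengths, bin, step = bin) {
  pieces <- lapply(names(chrom_lengths), function(ch) {
    w <- make_windows(chrom_lengths[[ch]], bin, step)
    cbind(chrom = ch, w)
  })
  do.call(rbind, pieces)
}

#' @export
print.window_stat <- function(x, ...) {
  cat("Sliding-window statistics: ", nrow(x), " windows on ",
      length(unique(x$chrom)), " chromosome(s); ",
      sum(x$excluded), " excluded (too few values)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.window_stat <- function(x, chrom = NULL, ...) {
  if (is.null(chrom)) chrom <- x$chrom[1]
  d <- x[x$chrom == chrom & !x$excluded, ]
  mid <- (d$start + d$end) / 2
  graphics::plot(mid, d$value, type = "l", xlab = paste0(chrom, " position (bp)"),
                 ylab = "value", ...)
  invisible(x)
}
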