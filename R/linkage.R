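# Genotype-dosage linkage disequilibrium: pairwise r-squared between sites,
# distance-binned decay curves, and windowed LD for site pairs 1-10 kb apart.
#
# r2 is the squared Pearson correlation of dosage vectors (0/1/2) over the
# complete-case sample intersection of the pair — computed directly from
# genotypes, so phase is irrelevant. Pairs where either restricted vector is
# constant are undefined and skipped (not counted as 0).

#' Genotype r-squared between two sites
#'
#' @param d1,d2 dosage vectors (0/1/2, `NA` = missing).
#' @return squared Pearson correlation over complete cases, or `NA` when
#'   fewer than two complete cases remain or either restricted vector is
#'   constant.
#' @export
genotype_r2 <- function(d1, d2) {
  cc <- !is.na(d1) & !is.na(d2)
  if (sum(cc) < 2) return(NA_real_)
  x <- d1[cc]
  y <- d2[cc]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# All intra-chromosomal site pairs with min_sep <= distance <= max_sep and
# their r2, computed blockwise with missing-data-aware cross-products.
# Returns data frame chrom, pos1, pos2, dist, r2 (NA-r2 pairs dropped).
pair_r2_table <- function(gm, min_sep = 1, max_sep, block = 512L) {
  res <- list()
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[idx]
    if (is.unsorted(pos)) stop("genotype matrix must be sorted by position")
    m <- length(pos)
    if (m < 2) next
    D <- gm$dosage[idx, , drop = FALSE]
    A <- D; A[is.na(A)] <- 0
    Nm <- (!is.na(D)) * 1
    A2 <- A * A
    j_lo <- findInterval(pos + min_sep - 0.5, pos) + 1L
    j_hi <- findInterval(pos + max_sep + 0.5, pos)
    j_lo <- pmax(j_lo, seq_len(m) + 1L)
    has <- j_hi >= j_lo
    if (!any(has)) next
    for (b0 in seq(1L, m, by = block)) {
      I <- b0:min(b0 + block - 1L, m)
      I <- I[has[I]]
      if (length(I) == 0) next
      Jmin <- min(j_lo[I]); Jmax <- max(j_hi[I])
      J <- Jmin:Jmax
      nij <- Nm[I, , drop = FALSE] %*% t(Nm[J, , drop = FALSE])
      sx  <- A[I, , drop = FALSE]  %*% t(Nm[J, , drop = FALSE])
      sy  <- Nm[I, , drop = FALSE] %*% t(A[J, , drop = FALSE])
      sxy <- A[I, , drop = FALSE]  %*% t(A[J, , drop = FALSE])
      sx2 <- A2[I, , drop = FALSE] %*% t(Nm[J, , drop = FALSE])
      sy2 <- Nm[I, , drop = FALSE] %*% t(A2[J, , drop = FALSE])
      cnt <- j_hi[I] - j_lo[I] + 1L
      ii <- rep(seq_along(I), cnt)
      jj <- unlist(lapply(seq_along(I), function(k) j_lo[I[k]]:j_hi[I[k]]))
      sel <- cbind(ii, jj - Jmin + 1L)
      n <- nij[sel]
      num <- n * sxy[sel] - sx[sel] * sy[sel]
      dx <- n * sx2[sel] - sx[sel]^2
      dy <- n * sy2[sel] - sy[sel]^2
      ok <- n >= 2 & dx > 0 & dy > 0
      if (!any(ok)) next
      r2 <- num[ok]^2 / (dx[ok] * dy[ok])
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch,
        pos1 = pos[I[ii[ok]]],
        pos2 = pos[jj[ok]],
        dist = pos[jj[ok]] - pos[I[ii[ok]]],
        r2 = r2, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(0), pos1 = integer(0),
                      pos2 = integer(0), dist = integer(0), r2 = numeric(0)))
  do.call(rbind, res)
}

#' Distance-binned LD-decay curve
#'
#' All intra-chromosomal site pairs with 0 < distance <= `max_dist`
#' contribute their r2 to the distance bin containing the pair's separation;
#' the curve reports mean r2 and pair count per bin, per chromosome.
#' Bins are `[0, w), [w, 2w), ...` with `w = bin_width`.
#'
#' @param gm a `genotype_matrix` (sorted by position).
#' @param max_dist maximum pair separation in bp (default 5000).
#' @param bin_width distance bin width in bp (default 10, which resolves
#'   decay on the sub-200 bp scale).
#' @return an `ld_decay` data frame: `chrom`, `bin_start`, `bin_end`,
#'   `mean_r2`, `n_pairs`. Empty (with a warning) when no eligible pairs
#'   exist.
#' @export
ld_decay <- function(gm, max_dist = 5000, bin_width = 10) {
  if (max_dist < bin_width) stop("max_dist must be >= bin_width")
  pairs <- pair_r2_table(gm, min_sep = 1, max_sep = max_dist)
  n_bins <- ceiling(max_dist / bin_width)
  template <- data.frame(bin_start = (seq_len(n_bins) - 1) * bin_width,
                         bin_end = pmin(seq_len(n_bins) * bin_width, max_dist))
  if (nrow(pairs) == 0) {
    warning("no eligible site pairs within max_dist")
    out <- template[0, ]
    out$chrom <- character(0); out$mean_r2 <- numeric(0)
    out$n_pairs <- integer(0)
    out <- out[, c("chrom", "bin_start", "bin_end", "mean_r2", "n_pairs")]
    class(out) <- c("ld_decay", "data.frame")
    return(out)
  }
  pieces <- lapply(split(pairs, pairs$chrom), function(d) {
    bin <- pmin(d$dist %/% bin_width + 1L, n_bins)
    mean_r2 <- rep(NA_real_, n_bins)
    n_pairs <- integer(n_bins)
    agg_n <- tapply(d$r2, bin, length)
    agg_m <- tapply(d$r2, bin, mean)
    k <- as.integer(names(agg_n))
    n_pairs[k] <- as.integer(agg_n)
    mean_r2[k] <- agg_m
    cbind(data.frame(chrom = d$chrom[1]), template,
          mean_r2 = mean_r2, n_pairs = n_pairs)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD-decay curve: ", length(unique(x$chrom)), " chromosome(s), ",
      sum(x$n_pairs), " pairs\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x[x$n_pairs > 0, ]), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.ld_decay <- function(x, ...) {
  d <- x[x$n_pairs > 0, ]
  mid <- (d$bin_start + d$bin_end) / 2
  graphics::plot(mid, d$mean_r2, xlab = "distance (bp)",
                 ylab = expression(mean ~ r^2), ylim = c(0, 1), type = "n", ...)
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, ]
    graphics::lines((dd$bin_start + dd$bin_end) / 2, dd$mean_r2)
  }
  invisible(x)
}

#' Windowed LD for site pairs 1-10 kb apart
#'
#' Every qualifying pair (`min_sep <= distance <= max_sep`) contributes its
#' r2 to the sliding window containing the pair anchor (midpoint by default,
#' left site optionally); windows with fewer than `min_pairs` contributing
#' pairs are excluded.
#'
#' @param gm a `genotype_matrix` (sorted).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param min_sep,max_sep pair separation range in bp (defaults 1000, 10000).
#' @param bin,step window size and step (defaults 100 kb, 50 kb).
#' @param min_pairs minimum contributing pairs per window (default 100).
#' @param anchor `"midpoint"` (default) or `"left"`.
#' @return a `window_stat` data frame of mean r2 per window.
#' @export
windowed_ld <- function(gm, chrom_lengths, min_sep = 1000, max_sep = 10000,
                        bin = 1e5, step = 5e4, min_pairs = 100,
                        anchor = c("midpoint", "left")) {
  if (min_sep > max_sep) stop("min_sep must not exceed max_sep")
  anchor <- match.arg(anchor)
  pairs <- pair_r2_table(gm, min_sep = min_sep, max_sep = max_sep)
  apos <- switch(anchor,
                 midpoint = (pairs$pos1 + pairs$pos2) %/% 2L,
                 left = pairs$pos1)
  ord <- order(pairs$chrom, apos)
  w <- windows_for_chroms(chrom_lengths, bin, step)
  aggregate_windows(pairs$chrom[ord], apos[ord], pairs$r2[ord], w,
                    stat = "mean", min_values = min_pairs)
}
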