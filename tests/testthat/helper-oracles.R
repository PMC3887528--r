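# Independent oracles: deliberately naive implementations (enumeration,
# double loops, scalar transcriptions of published formulas) used to check
# the package's vectorized estimators.

# Nucleotide diversity as the literal fraction of mismatching allele pairs
# over all C(n, 2) pairs of called alleles.
oracle_pi <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)], function(d) {
    c(rep(1, d), rep(0, 2 - d))
  }))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  mism <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    mism <- mism + (alleles[i] != alleles[j])
  mism / choose(n, 2)
}

# Scalar transcription of the Weir & Cockerham (1984) variance components
# for one biallelic site in diploids.
oracle_wc <- function(dos_by_pop) {
  dos_by_pop <- lapply(dos_by_pop, function(d) d[!is.na(d)])
  r <- length(dos_by_pop)
  n_i <- sapply(dos_by_pop, length)
  if (any(n_i == 0)) return(c(a = NA, b = NA, c = NA))
  p_i <- sapply(dos_by_pop, function(d) sum(d) / (2 * length(d)))
  h_i <- sapply(dos_by_pop, function(d) sum(d == 1) / length(d))
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# r2 by the definitional route: Pearson correlation over complete cases.
oracle_r2 <- function(d1, d2) {
  cc <- !is.na(d1) & !is.na(d2)
  if (sum(cc) < 2) return(NA_real_)
  x <- d1[cc]; y <- d2[cc]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# LD-decay curve by brute-force double loop over all site pairs.
oracle_ld_decay <- function(gm, max_dist, bin_width) {
  n_bins <- ceiling(max_dist / bin_width)
  acc <- lapply(unique(gm$sites$chrom), function(ch) {
    idx <- which(gm$sites$chrom == ch)
    sums <- numeric(n_bins); cnts <- integer(n_bins)
    if (length(idx) >= 2) {
      for (ii in 1:(length(idx) - 1)) for (jj in (ii + 1):length(idx)) {
        d <- gm$sites$pos[idx[jj]] - gm$sites$pos[idx[ii]]
        if (d < 1 || d > max_dist) next
        r2 <- oracle_r2(gm$dosage[idx[ii], ], gm$dosage[idx[jj], ])
        if (is.na(r2)) next
        b <- min(d %/% bin_width + 1, n_bins)
        sums[b] <- sums[b] + r2
        cnts[b] <- cnts[b] + 1L
      }
    }
    data.frame(chrom = ch,
               bin_start = (seq_len(n_bins) - 1) * bin_width,
               mean_r2 = ifelse(cnts > 0, sums / cnts, NA),
               n_pairs = cnts)
  })
  do.call(rbind, acc)
}

# Window aggregation by per-window rescan.
oracle_windows <- function(chrom, pos, value, windows, stat, min_values) {
  out <- windows
  out$n_values <- NA_integer_; out$value <- NA_real_
  for (w in seq_len(nrow(windows))) {
    sel <- chrom == windows$chrom[w] &
      pos > windows$start[w] & pos <= windows$end[w]
    out$n_values[w] <- sum(sel)
    if (sum(sel) > 0)
      out$value[w] <- if (stat == "mean") mean(value[sel]) else sum(value[sel])
    else if (stat == "sum") out$value[w] <- 0
  }
  out$excluded <- out$n_values < min_values
  out$value[out$excluded] <- NA_real_
  out
}
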