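# Per-site and windowed nucleotide diversity (pi), SNP density, and
# Weir & Cockerham (1984) F_ST from genotype dosages.
#
# Missing genotypes are handled complete-case per site: the called allele
# count n and per-population sample sizes are recomputed at every site.

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity: with `n` called alleles of which `j`
#' are the alternate allele, `pi = 2 j (n - j) / (n (n - 1))` — the fraction
#' of mismatching pairs among all C(n, 2) allele pairs. Sites with fewer
#' than two called alleles are undefined (`NA`).
#'
#' @param d dosage vector for one site (0/1/2, `NA` = missing genotype).
#' @return per-site pi in \[0, 1\].
#' @export
site_pi <- function(d) {
  n <- 2 * sum(!is.na(d))
  if (n < 2) return(NA_real_)
  j <- sum(d, na.rm = TRUE)
  2 * j * (n - j) / (n * (n - 1))
}

#' Per-site pi for every site of a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @return data frame `chrom`, `pos`, `pi`, `n_alleles` (called allele
#'   count); undefined sites carry `pi = NA` and a notice is emitted.
#' @export
site_pi_table <- function(gm) {
  d <- gm$dosage
  n <- 2 * rowSums(!is.na(d))
  j <- rowSums(d, na.rm = TRUE)
  pi <- ifelse(n >= 2, 2 * j * (n - j) / (n * pmax(n - 1, 1)), NA_real_)
  if (any(n < 2))
    message(sum(n < 2), " site(s) with < 2 called alleles skipped (pi undefined)")
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
             pi = pi, n_alleles = as.integer(n), stringsAsFactors = FALSE)
}

#' Windowed nucleotide diversity
#'
#' Each window's value is the sum of per-site pi within the window divided
#' by the window length in bp: monomorphic and unascertained bases contribute
#' zero to the numerator but are part of the denominator, so pi is defined
#' over all bases and empty windows are 0, not excluded.
#'
#' @param pi_df output of [site_pi_table()] (sorted by position within
#'   chromosome); `NA` pi sites are dropped.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin,step window size and step in bp (default 100 kb tiling).
#' @return a `window_stat` data frame; `value` is pi per bp.
#' @export
windowed_pi <- function(pi_df, chrom_lengths, bin = 1e5, step = bin) {
  keep <- !is.na(pi_df$pi)
  w <- windows_for_chroms(chrom_lengths, bin, step)
  out <- aggregate_windows(pi_df$chrom[keep], pi_df$pos[keep],
                           pi_df$pi[keep], w, stat = "sum", min_values = 0)
  out$value <- out$value / (out$end - out$start)
  out
}

#' SNP density as "1 SNP per X bases"
#'
#' @param pos SNP positions within the span (only the count is used).
#' @param span_length span length in bp (> 0).
#' @return X = span length / SNP count; `NA` when there are no SNPs.
#' @export
snp_density <- function(pos, span_length) {
  if (length(span_length) != 1 || is.na(span_length) || span_length <= 0)
    stop("span_length must be a positive scalar")
  n <- length(pos)
  if (n == 0) return(NA_real_)
  span_length / n
}

#' Weir-Cockerham variance components for one site
#'
#' Computes the Weir & Cockerham (1984) components for a biallelic site in
#' diploids: `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals), from per-population sample
#' sizes, alternate-allele frequencies and observed heterozygote frequencies.
#'
#' @param dosages_by_population list of dosage vectors, one per population.
#' @return named numeric `c(a =, b =, c =)`; all `NA` when any population
#'   has no called genotype or only one individual is called per population.
#' @export
wc_fst_site <- function(dosages_by_population) {
  r <- length(dosages_by_population)
  if (r < 2) stop("need at least two populations")
  ni <- vapply(dosages_by_population, function(d) sum(!is.na(d)), 0)
  if (any(ni == 0)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  pi_ <- vapply(dosages_by_population, function(d) mean(d, na.rm = TRUE) / 2, 0)
  hi <- vapply(dosages_by_population, function(d) mean(d == 1, na.rm = TRUE), 0)
  wc_components(matrix(ni, 1), matrix(pi_, 1), matrix(hi, 1))[1, ]
}

# Vectorized WC (1984) components. ni/p/h are sites x populations matrices of
# per-site called-individual counts, alt-allele frequencies and observed
# heterozygote frequencies.
wc_components <- function(ni, p, h) {
  r <- ncol(ni)
  N <- rowSums(ni)
  nbar <- N / r
  nc <- (N - rowSums(ni^2) / N) / (r - 1)
  pbar <- rowSums(ni * p) / N
  s2 <- rowSums(ni * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * h) / N
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- nbar <= 1 | nc <= 0 | apply(ni == 0, 1, any)
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  cbind(a = a, b = b, c = cc)
}

#' Weir-Cockerham components for every site of a genotype matrix
#'
#' @param gm a `genotype_matrix` with at least two population labels.
#' @return a `fst_components` data frame: `chrom`, `pos`, `a`, `b`, `c`.
#'   Sites where a population is entirely missing are `NA` (skipped in
#'   aggregation).
#' @export
wc_fst_components <- function(gm) {
  pops <- unique(gm$populations)
  if (length(pops) < 2)
    stop("F_ST needs at least two populations; found: ",
         paste(pops, collapse = ", "))
  d <- gm$dosage
  ni <- p <- h <- matrix(0, nrow(d), length(pops))
  for (k in seq_along(pops)) {
    dk <- d[, gm$populations == pops[k], drop = FALSE]
    nk <- rowSums(!is.na(dk))
    ni[, k] <- nk
    p[, k] <- ifelse(nk > 0, rowSums(dk, na.rm = TRUE) / (2 * nk), NA)
    h[, k] <- ifelse(nk > 0, rowSums(dk == 1, na.rm = TRUE) / nk, NA)
  }
  comp <- wc_components(ni, p, h)
  structure(data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                       a = comp[, "a"], b = comp[, "b"], c = comp[, "c"],
                       stringsAsFactors = FALSE),
            class = c("fst_components", "data.frame"))
}

#' Weighted (ratio-of-sums) F_ST over sites
#'
#' `sum(a) / sum(a + b + c)` over sites with `a + b + c > 0`; negative
#' per-site components are retained in the sums (no truncation), preserving
#' the near-unbiasedness of the ratio-of-sums estimator. Usable per window,
#' per chromosome arm, or genome-wide.
#'
#' @param comp a `fst_components` data frame (or anything with columns
#'   `a`, `b`, `c`).
#' @return weighted F_ST; `NA` when no usable site remains.
#' @export
wc_fst_aggregate <- function(comp) {
  s <- comp$a + comp$b + comp$c
  use <- !is.na(s) & s > 0
  if (!any(use)) return(NA_real_)
  sum(comp$a[use]) / sum(s[use])
}

#' Sliding-window F_ST
#'
#' Per-window ratio of sums of the Weir-Cockerham components; windows with
#' fewer than `min_values` usable sites are excluded, following the
#' figure-caption rule for thin windows.
#'
#' @param comp a `fst_components` data frame.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin,step window size and step (default 100 kb / 50 kb).
#' @param min_values minimum usable sites per window (default 100).
#' @return a `window_stat` data frame.
#' @export
fst_windows <- function(comp, chrom_lengths, bin = 1e5, step = 5e4,
                        min_values = 100) {
  s <- comp$a + comp$b + comp$c
  use <- !is.na(s) & s > 0
  w <- windows_for_chroms(chrom_lengths, bin, step)
  num <- aggregate_windows(comp$chrom[use], comp$pos[use], comp$a[use],
                           w, stat = "sum", min_values = 0)
  den <- aggregate_windows(comp$chrom[use], comp$pos[use], s[use],
                           w, stat = "sum", min_values = 0)
  out <- num
  out$value <- ifelse(den$value != 0, num$value / den$value, NA_real_)
  out$excluded <- out$n_values < min_values
  out$value[out$excluded] <- NA_real_
  out
}
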