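# Synthetic-data generator reproducing the statistical structure the
# analyses assume: two diverged populations (Balding-Nichols allele
# frequencies around a neutral-SFS ancestral frequency), recombination-driven
# LD decay via a founder-mosaic copying model, inversion intervals where
# switching is suppressed in heterokaryotypes, a centromeric low-
# recombination zone, and GATK-style site annotations with engineered
# filter failures for exercising the cascade.
#
# Determinism: a single master seed with fixed per-stage offsets —
# simulate_founders() uses seed, simulate_population() seed + 1,
# emit_vcf()/annotation drawing seed + 2, simulate_depth() seed + 3 — so
# each stage is reproducible in isolation and end-to-end.

#' Simulation configuration
#'
#' Defaults encode the study design the package targets: 24 diploids split
#' 20/4 over two populations (a local and a distant one), Balding-Nichols
#' divergence `theta_fst = 0.057` (theta equals the expected F_ST), a
#' desk-scale 1 Mb chromosome carrying 5,000 SNPs (about 1 SNP / 200 bp), a
#' per-bp haplotype switch rate of 4e-3 (mean r2 drops below 0.2 within
#' about 200 bp), one polymorphic inversion with fully suppressed switching
#' in heterokaryotypes, a centromeric low-recombination zone, and a
#' per-genotype missing rate of 0.024 (about 44% of sites then fail the
#' called-in-all-samples rule for 24 samples).
#'
#' @param seed master RNG seed (mandatory; there is no implicit entropy).
#' @param n_sites number of SNP sites.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param n_founders ancestral founder haplotypes (neutral SFS is defined
#'   over these).
#' @param panel_size per-population copying-panel size; default
#'   `2 * n_per_pop` for each population, which makes site-wise allele
#'   counts exactly binomial when `switch_rate = 0`.
#' @param switch_rate per-bp probability that a descendant haplotype
#'   switches copying source.
#' @param theta_fst Balding-Nichols divergence parameter in \[0, 1\].
#' @param n_per_pop named vector of diploids per population; a single
#'   unnamed value gives one population.
#' @param inversions list of inversions, each a list with `name`, `start`,
#'   `end` (0-based half-open), `suppression` (factor multiplying the switch
#'   rate inside the inversion for heterokaryotypes, 0 = no crossing over),
#'   `inv_freq` (inverted-arrangement frequency) or explicit `karyotypes`
#'   (0/1/2 inverted copies per sample).
#' @param centromere list with `start`, `end`, `suppression` (applies to all
#'   karyotypes), or `NULL`.
#' @param telomere list with `start`, `end` (reporting region only).
#' @param missing_rate per-genotype missing probability.
#' @param engineered fractions of sites engineered to fail each filter
#'   stage; see Details.
#' @param annotation_law means/ranges for the passing INFO annotations.
#'
#' @details `engineered` is a list of fractions: `qd`, `mq`, `fs`,
#' `haplotype_score`, `mq_rank_sum`, `read_pos_rank_sum` (hard-filter tag
#' failures), `low_qual` (QUAL <= 4), `missing` (one genotype forced
#' missing), `not_in_hc` (left out of the high-confidence set),
#' `low_carrier` (minor allele rewritten to 4 carriers), `multiallelic`
#' (second non-reference allele added). Subsets are disjoint, so each
#' engineered site has a known first-failing stage recorded in the truth
#' table.
#'
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_sites = 5000,
                       chrom = "2R",
                       chrom_length = 1e6,
                       n_founders = 8,
                       panel_size = NULL,
                       switch_rate = 4e-3,
                       theta_fst = 0.057,
                       n_per_pop = c(Tanzania = 20, Cameroon = 4),
                       inversions = list(list(name = "2Rb", start = 3e5,
                                              end = 5e5, suppression = 0,
                                              inv_freq = 0.5)),
                       centromere = list(start = 9.2e5, end = 1e6,
                                         suppression = 0.1),
                       telomere = list(start = 0, end = 3e4),
                       missing_rate = 0.024,
                       engineered = list(),
                       annotation_law = list()) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory (no implicit entropy)")
  eng_default <- list(qd = 0.01, mq = 0.01, fs = 0.005,
                      haplotype_score = 0.005, mq_rank_sum = 0.005,
                      read_pos_rank_sum = 0.005, low_qual = 0.01,
                      missing = 0, not_in_hc = 0.1, low_carrier = 0.02,
                      multiallelic = 0.03, low_carrier_n = 4)
  eng <- utils::modifyList(eng_default, engineered)
  ann_default <- list(qual = c(40, 900), qd = c(5, 35), mq = c(45, 60),
                      fs = c(0, 20), haplotype_score = c(0, 5),
                      mq_rank_sum = c(-5, 5), read_pos_rank_sum = c(-4, 4),
                      dp = c(60, 200))
  ann <- utils::modifyList(ann_default, annotation_law)
  if (is.null(names(n_per_pop)))
    names(n_per_pop) <- paste0("pop", seq_along(n_per_pop))
  cfg <- list(seed = as.integer(seed), n_sites = n_sites, chrom = chrom,
              chrom_length = chrom_length, n_founders = n_founders,
              panel_size = panel_size, switch_rate = switch_rate,
              theta_fst = theta_fst, n_per_pop = n_per_pop,
              inversions = inversions, centromere = centromere,
              telomere = telomere, missing_rate = missing_rate,
              engineered = eng, annotation_law = ann)
  rates <- c(switch_rate, theta_fst, missing_rate,
             unlist(eng[setdiff(names(eng), "low_carrier_n")]))
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (switch_rate >= 1) stop("switch_rate must be < 1")
  if (n_sites > chrom_length) stop("n_sites exceeds chrom_length")
  if (n_founders < 2) stop("need at least 2 founders")
  for (iv in inversions) {
    if (iv$start < 0 || iv$end > chrom_length || iv$start >= iv$end)
      stop("inversion interval outside chromosome")
    if (iv$suppression < 0 || iv$suppression > 1)
      stop("suppression factor must lie in [0, 1]")
    if (!is.null(iv$karyotypes) && !all(iv$karyotypes %in% 0:2))
      stop("invalid karyotype label (must be 0, 1 or 2 inverted copies)")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", x$n_sites, " sites on ", x$chrom, " (",
      format(x$chrom_length, big.mark = ","), " bp), ",
      sum(x$n_per_pop), " diploids in ", length(x$n_per_pop),
      " population(s), theta = ", x$theta_fst,
      ", switch rate = ", x$switch_rate, "/bp, seed = ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Simulate the ancestral founder panel
#'
#' Biallelic sites at positions uniform on the chromosome, with ancestral
#' allele frequencies drawn from the neutral site-frequency spectrum over
#' the founders: P(derived count = i) proportional to 1/i, i = 1..K-1.
#'
#' @param config a [sim_config()].
#' @return a `sim_founders` list: `pos`, `ref`, `alt`, `alleles`
#'   (founders x sites 0/1 matrix), `p_anc`.
#' @export
simulate_founders <- function(config) {
  set.seed(config$seed)
  K <- config$n_founders
  n <- config$n_sites
  pos <- sort(sample.int(config$chrom_length, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  sfs_p <- (1 / seq_len(K - 1)) / sum(1 / seq_len(K - 1))
  cnt <- sample.int(K - 1, n, replace = TRUE, prob = sfs_p)
  alleles <- matrix(0L, K, n)
  for (s in seq_len(n)) alleles[sample.int(K, cnt[s]), s] <- 1L
  structure(list(pos = pos, ref = unname(ref), alt = unname(alt),
                 alleles = alleles, p_anc = cnt / K, config = config),
            class = "sim_founders")
}

# Per-gap suppressed ("effective") lengths. pos sorted 1-based; intervals
# 0-based half-open. Returns matrix gaps x (1 + n_inversions): column 1 is
# the gap length after centromere suppression only; remaining columns give
# the additional bp to suppress per inversion when heterokaryotypic.
gap_overlaps <- function(pos, config) {
  d <- diff(pos)
  g1 <- pos[-length(pos)]  # gap covers 0-based [g1, g2)
  g2 <- pos[-1]
  ov <- function(s0, e0) pmax(0, pmin(g2, e0) - pmax(g1, s0))
  base <- d
  if (!is.null(config$centromere)) {
    o <- ov(config$centromere$start, config$centromere$end)
    base <- base - o * (1 - config$centromere$suppression)
  }
  inv_cols <- lapply(config$inversions, function(iv)
    ov(iv$start, iv$end) * (1 - iv$suppression))
  cbind(base, do.call(cbind, c(inv_cols, list(deparse.level = 0))))
}

#' Simulate diploid populations from the founder panel
#'
#' For each population, per-site allele frequencies are drawn from the
#' Balding-Nichols model, `Beta(p (1 - theta) / theta, (1 - p) (1 - theta) /
#' theta)` around the ancestral frequency `p`; a population copying panel of
#' haplotypes is drawn at those frequencies (the ancestral founders
#' themselves when `theta = 0` and the panel size equals `n_founders`).
#' Each descendant haplotype is then a mosaic over the panel with per-bp
#' switch probability `switch_rate`, multiplied by the suppression factor
#' inside the centromere (all karyotypes) and inside each inversion for
#' heterokaryotypes only — homokaryotypes recombine freely, emulating the
#' lack of crossing over in inversion heterozygotes.
#'
#' @param founders a `sim_founders` object.
#' @param config a [sim_config()]; defaults to the one inside `founders`.
#' @return list with `matrix` (a `genotype_matrix`) and `truth` (list:
#'   `p_anc`, `p_pop`, `karyotypes`, `n_switches`).
#' @export
simulate_population <- function(founders, config = founders$config) {
  set.seed(config$seed + 1L)
  n <- config$n_sites
  pos <- founders$pos
  pops <- names(config$n_per_pop)
  n_ind_total <- sum(config$n_per_pop)
  theta <- config$theta_fst
  ovl <- gap_overlaps(pos, config)
  n_inv <- length(config$inversions)

  # karyotypes per individual per inversion (0/1/2 inverted copies)
  kary <- matrix(0L, n_ind_total, max(n_inv, 1))
  for (j in seq_len(n_inv)) {
    iv <- config$inversions[[j]]
    if (!is.null(iv$karyotypes)) {
      if (length(iv$karyotypes) != n_ind_total)
        stop("explicit karyotypes must cover all ", n_ind_total, " samples")
      kary[, j] <- as.integer(iv$karyotypes)
    } else {
      kary[, j] <- stats::rbinom(n_ind_total, 2, iv$inv_freq %||% 0.5)
    }
  }

  dosage <- matrix(NA_integer_, n, n_ind_total)
  p_pop <- matrix(NA_real_, n, length(pops), dimnames = list(NULL, pops))
  n_switches <- integer(2 * n_ind_total)
  ind0 <- 0L
  for (k in seq_along(pops)) {
    n_ind <- config$n_per_pop[[k]]
    p <- founders$p_anc
    if (theta == 0) {
      pk <- p
    } else if (theta == 1) {
      pk <- stats::rbinom(n, 1, p)
    } else {
      pk <- stats::rbeta(n, p * (1 - theta) / theta,
                         (1 - p) * (1 - theta) / theta)
    }
    p_pop[, k] <- pk
    Kp <- config$panel_size %||% (2L * n_ind)
    if (theta == 0 && Kp == config$n_founders) {
      panel <- founders$alleles
    } else {
      panel <- matrix(stats::rbinom(Kp * n, 1, rep(pk, each = Kp)), Kp, n)
    }
    # haplotypes start on a random permutation of the panel (each founder
    # used equally often; exactly once when Kp == 2 * n_ind, which makes
    # site-wise allele counts exactly binomial at switch_rate = 0)
    start_f <- sample(rep_len(seq_len(Kp), 2L * n_ind))
    for (i in seq_len(n_ind)) {
      gi <- ind0 + i
      het <- kary[gi, ] == 1L
      eff <- ovl[, 1]
      if (n_inv > 0)
        for (j in seq_len(n_inv)) if (het[j]) eff <- eff - ovl[, j + 1]
      eff <- pmax(eff, 0)
      p_sw <- if (config$switch_rate == 0) rep(0, n - 1)
              else -expm1(eff * log1p(-config$switch_rate))
      for (h in 1:2) {
        hl <- 2L * (gi - 1L) + h        # global haplotype index
        hp <- 2L * (i - 1L) + h         # population-local haplotype index
        f0 <- start_f[hp]
        sw <- which(stats::runif(n - 1) < p_sw)
        n_switches[hl] <- length(sw)
        f_seq <- integer(length(sw) + 1L)
        f_seq[1] <- f0
        if (length(sw)) {
          for (q in seq_along(sw)) {
            cur <- f_seq[q]
            nxt <- sample.int(Kp - 1L, 1L)
            f_seq[q + 1L] <- if (nxt >= cur) nxt + 1L else nxt
          }
        }
        seg_len <- diff(c(0L, sw, n))
        f <- rep(f_seq, seg_len)
        hap <- panel[cbind(f, seq_len(n))]
        if (h == 1L) tmp <- hap else dosage[, gi] <- tmp + hap
      }
    }
    ind0 <- ind0 + n_ind
  }
  if (config$missing_rate > 0) {
    na_mask <- matrix(stats::runif(n * n_ind_total) < config$missing_rate,
                      n, n_ind_total)
    dosage[na_mask] <- NA_integer_
  }
  samples <- unlist(lapply(seq_along(pops), function(k)
    sprintf("%s%02d", pops[k], seq_len(config$n_per_pop[[k]]))))
  populations <- setNames(rep(pops, config$n_per_pop), samples)
  sites <- data.frame(chrom = config$chrom, pos = pos,
                      ref = founders$ref, alt = founders$alt,
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, dosage, samples, populations)
  kary_df <- if (n_inv > 0) {
    do.call(rbind, lapply(seq_len(n_inv), function(j)
      data.frame(sample = samples,
                 inversion = config$inversions[[j]]$name %||% paste0("inv", j),
                 karyotype = kary[, j], stringsAsFactors = FALSE)))
  } else {
    data.frame(sample = character(0), inversion = character(0),
               karyotype = integer(0))
  }
  list(matrix = gm,
       truth = list(p_anc = founders$p_anc, p_pop = p_pop,
                    karyotypes = kary_df, n_switches = n_switches))
}

eng_hard_tags <- c(qd = "QD", mq = "MQ", fs = "FS",
                   haplotype_score = "HaplotypeScore",
                   mq_rank_sum = "MQRankSum",
                   read_pos_rank_sum = "ReadPosRankSum")

#' Emit the simulated call set as VCF plus side files
#'
#' Wraps the simulated genotype matrix in a VCF with GT and GATK-style INFO
#' annotations drawn from the configured annotation law, engineering a
#' configurable fraction of sites to fail each hard-filter tag and each
#' cascade rule (disjoint subsets, with the intended first-failing stage
#' recorded in the truth table). Also produces the matching high-confidence
#' call set (three synthetic high-coverage samples; the `not_in_hc` subset
#' is left out), the sample-to-population table, and the region BED
#' (inversions, centromere, telomere).
#'
#' @param sim output of [simulate_population()].
#' @param dir output directory, or `NULL` to return in-memory objects only.
#' @param config the [sim_config()] used to build `sim`.
#' @return list with `low` and `hc` (`vcf_sites`), `hc_keys`, `truth`
#'   (per-site engineered stage table), `populations`, `regions`, and — when
#'   `dir` is given — `paths` to low.vcf, hc.vcf, populations.tsv,
#'   regions.bed, truth.tsv, karyotypes.tsv.
#' @export
emit_vcf <- function(sim, dir = NULL, config) {
  set.seed(config$seed + 2L)
  gm <- sim$matrix
  n <- nrow(gm$sites)
  n_ind <- length(gm$samples)
  eng <- config$engineered
  law <- config$annotation_law
  runif_in <- function(m, range) stats::runif(m, range[1], range[2])

  qual <- runif_in(n, law$qual)
  info <- data.frame(QD = runif_in(n, law$qd),
                     MQ = runif_in(n, law$mq),
                     FS = runif_in(n, law$fs),
                     HaplotypeScore = runif_in(n, law$haplotype_score),
                     MQRankSum = runif_in(n, law$mq_rank_sum),
                     ReadPosRankSum = runif_in(n, law$read_pos_rank_sum),
                     DP = round(runif_in(n, law$dp)))
  info[] <- lapply(info, function(v) round(v, 4))
  qual <- round(qual, 2)

  # disjoint engineered subsets, in cascade order
  fracs <- c(qd = eng$qd, mq = eng$mq, fs = eng$fs,
             haplotype_score = eng$haplotype_score,
             mq_rank_sum = eng$mq_rank_sum,
             read_pos_rank_sum = eng$read_pos_rank_sum,
             low_qual = eng$low_qual, missing = eng$missing,
             not_in_hc = eng$not_in_hc, low_carrier = eng$low_carrier,
             multiallelic = eng$multiallelic)
  pool <- sample.int(n)
  counts <- floor(fracs * n)
  if (sum(counts) > n) stop("engineered fractions sum past 1")
  subsets <- list()
  off <- 0L
  for (nm in names(counts)) {
    subsets[[nm]] <- if (counts[nm] > 0) pool[off + seq_len(counts[nm])]
                     else integer(0)
    off <- off + counts[nm]
  }
  fail_ranges <- list(qd = c(0, 1.9), mq = c(10, 39), fs = c(61, 100),
                      haplotype_score = c(13.5, 30),
                      mq_rank_sum = c(-20, -13),
                      read_pos_rank_sum = c(-15, -8.5))
  for (nm in names(fail_ranges)) {
    s <- subsets[[nm]]
    if (length(s))
      info[[eng_hard_tags[nm]]][s] <- round(runif_in(length(s),
                                                     fail_ranges[[nm]]), 4)
  }
  if (length(subsets$low_qual))
    qual[subsets$low_qual] <- round(runif_in(length(subsets$low_qual),
                                             c(0.5, 3.9)), 2)

  dosage <- gm$dosage
  for (s in subsets$missing) {
    dosage[s, sample.int(n_ind, 1)] <- NA_integer_
  }
  lc <- eng$low_carrier_n
  for (s in subsets$low_carrier) {
    row <- rep(0L, n_ind)
    row[sample.int(n_ind, min(lc, n_ind))] <- 1L
    dosage[s, ] <- row
  }
  # dosage 0 -> 0/0, 1 -> 0/1, 2 -> 1/1
  gt1 <- matrix(ifelse(is.na(dosage), NA_integer_,
                       ifelse(dosage == 2, 1L, 0L)), n, n_ind)
  gt2 <- matrix(ifelse(is.na(dosage), NA_integer_,
                       ifelse(dosage >= 1, 1L, 0L)), n, n_ind)

  alt <- gm$sites$alt
  bases <- c("A", "C", "G", "T")
  for (s in subsets$multiallelic) {
    alt2 <- setdiff(bases, c(gm$sites$ref[s], alt[s]))[1]
    alt[s] <- paste0(alt[s], ",", alt2)
    gt1[s, ] <- 1L
    gt2[s, ] <- 1L
    carriers2 <- sample.int(n_ind, min(max(5, eng$low_carrier_n + 1), n_ind))
    gt2[s, carriers2] <- 2L
  }

  low <- new_vcf_sites(gm$sites$chrom, gm$sites$pos, gm$sites$ref, alt,
                       qual, info, gt1, gt2, gm$samples)

  in_hc <- !(seq_len(n) %in% subsets$not_in_hc)
  hc_keys <- site_key(gm$sites$chrom[in_hc], gm$sites$pos[in_hc],
                      gm$sites$ref[in_hc], gm$sites$alt[in_hc])
  # matching high-coverage call set: 3 synthetic samples, everything passing
  hcn <- sum(in_hc)
  hc_p <- sim$truth$p_anc[in_hc]
  hc_dos <- matrix(stats::rbinom(hcn * 3, 2, rep(hc_p, 3)), hcn, 3)
  hc_info <- data.frame(QD = round(runif_in(hcn, c(10, 35)), 4),
                        MQ = round(runif_in(hcn, c(45, 60)), 4),
                        FS = round(runif_in(hcn, c(0, 20)), 4),
                        HaplotypeScore = round(runif_in(hcn, c(0, 5)), 4),
                        MQRankSum = round(runif_in(hcn, c(-5, 5)), 4),
                        ReadPosRankSum = round(runif_in(hcn, c(-4, 4)), 4),
                        DP = round(runif_in(hcn, c(40, 200))))
  hc <- new_vcf_sites(gm$sites$chrom[in_hc], gm$sites$pos[in_hc],
                      gm$sites$ref[in_hc], gm$sites$alt[in_hc],
                      round(runif_in(hcn, c(31, 900)), 2), hc_info,
                      matrix(ifelse(hc_dos == 2, 1L, 0L), hcn, 3),
                      matrix(ifelse(hc_dos >= 1, 1L, 0L), hcn, 3),
                      c("HC1", "HC2", "HC3"))

  stage <- rep("none", n)
  for (nm in names(eng_hard_tags)) stage[subsets[[nm]]] <- "hard_filter"
  stage[subsets$low_qual] <- "hard_filter"
  stage[subsets$missing] <- "not_called_in_all"
  stage[subsets$not_in_hc] <- "not_in_high_confidence"
  stage[subsets$low_carrier] <- "minor_allele_carriers"
  stage[subsets$multiallelic] <- "multiallelic"
  tag <- rep(NA_character_, n)
  for (nm in names(eng_hard_tags)) tag[subsets[[nm]]] <- eng_hard_tags[[nm]]
  tag[subsets$low_qual] <- "QUAL"
  truth <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                      engineered_stage = stage, engineered_tag = tag,
                      p_anc = sim$truth$p_anc, stringsAsFactors = FALSE)
  for (k in colnames(sim$truth$p_pop))
    truth[[paste0("p_", k)]] <- sim$truth$p_pop[, k]

  pops_df <- data.frame(sample = gm$samples, population = gm$populations,
                        stringsAsFactors = FALSE)
  regions <- list()
  for (iv in config$inversions)
    regions[[length(regions) + 1]] <-
      data.frame(name = iv$name %||% "inversion", chrom = config$chrom,
                 start = iv$start, end = iv$end)
  if (!is.null(config$centromere))
    regions[[length(regions) + 1]] <-
      data.frame(name = "centromere", chrom = config$chrom,
                 start = config$centromere$start, end = config$centromere$end)
  if (!is.null(config$telomere))
    regions[[length(regions) + 1]] <-
      data.frame(name = "telomere", chrom = config$chrom,
                 start = config$telomere$start, end = config$telomere$end)
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(name = character(0), chrom = character(0),
                             start = numeric(0), end = numeric(0))
  class(regions) <- c("region_set", "data.frame")

  out <- list(low = low, hc = hc, hc_keys = hc_keys, truth = truth,
              populations = pops_df, regions = regions)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(low = file.path(dir, "low.vcf"),
                  hc = file.path(dir, "hc.vcf"),
                  populations = file.path(dir, "populations.tsv"),
                  regions = file.path(dir, "regions.bed"),
                  truth = file.path(dir, "truth.tsv"),
                  karyotypes = file.path(dir, "karyotypes.tsv"))
    write_vcf(low, paths$low)
    write_vcf(hc, paths$hc)
    write_populations(pops_df, paths$populations)
    write_regions(regions, paths$regions)
    write_tsv(truth, paths$truth)
    write_tsv(sim$truth$karyotypes, paths$karyotypes)
    out$paths <- paths
  }
  out
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: founders, populations, and the emitted call set in
#' one call.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (see [emit_vcf()]).
#' @return list with `founders`, `population` and the [emit_vcf()] output
#'   under `files`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  founders <- simulate_founders(config)
  pop <- simulate_population(founders, config)
  files <- emit_vcf(pop, dir = dir, config = config)
  list(founders = founders, population = pop, files = files)
}

#' Simulate a per-base depth table
#'
#' Per-base depths are Poisson around `mean_depth`, depressed inside the
#' centromere and telomere (repetitive, poorly mapping regions), emulating
#' combined depth-of-coverage output. Zero-depth bases are omitted from the
#' table, matching the depth-table convention.
#'
#' @param config a [sim_config()].
#' @param mean_depth mean combined depth on the accessible background.
#' @param suppressed_mean mean depth inside centromere/telomere.
#' @return data frame `chrom`, `pos`, `depth` (depth > 0 rows only).
#' @export
simulate_depth <- function(config, mean_depth = 45, suppressed_mean = 0.8) {
  set.seed(config$seed + 3L)
  L <- config$chrom_length
  lambda <- rep(mean_depth, L)
  for (iv in list(config$centromere, config$telomere)) {
    if (!is.null(iv)) lambda[(iv$start + 1):iv$end] <- suppressed_mean
  }
  depth <- stats::rpois(L, lambda)
  keep <- depth > 0
  data.frame(chrom = config$chrom, pos = which(keep), depth = depth[keep],
             stringsAsFactors = FALSE)
}
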