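# Two-tier variant filtering: GATK-style hard filters plus construction of a
# high-confidence reference SNP set from high-coverage samples, then a
# four-rule exclusion cascade on the jointly called low-coverage sample set,
# with a per-stage accounting ledger.
#
# All annotation thresholds are strict inequalities exactly as conventionally
# printed (QD < 2.0 fails, MQ = 40 passes); an absent tag never fails a
# filter, because the caller omits rank-sum annotations at homozygous sites
# and absence carries no evidence.

#' Hard-filter thresholds
#'
#' Defaults are the standard GATK hard-filter recommendations for SNPs:
#' a site fails when QD < 2.0, MQ < 40, FS > 60, HaplotypeScore > 13,
#' MQRankSum < -12.5 or ReadPosRankSum < -8.0. `qual_min` and `depth_min`
#' are retention bounds (site kept only when QUAL > `qual_min` and
#' DP > `depth_min`) and are unset by default; the high-confidence tier uses
#' 30/30 and the low-coverage tier uses QUAL > 4 with no depth bound.
#'
#' @param qd_min,mq_min,fs_max,haplotype_score_max,mq_rank_sum_min,read_pos_rank_sum_min
#'   annotation thresholds (strict inequalities).
#' @param qual_min,depth_min strict lower retention bounds on QUAL and DP;
#'   `NA` disables the bound.
#' @return a `hard_filter_thresholds` list.
#' @export
hard_filter_thresholds <- function(qd_min = 2.0, mq_min = 40, fs_max = 60,
                                   haplotype_score_max = 13,
                                   mq_rank_sum_min = -12.5,
                                   read_pos_rank_sum_min = -8.0,
                                   qual_min = NA, depth_min = NA) {
  th <- list(qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
             haplotype_score_max = haplotype_score_max,
             mq_rank_sum_min = mq_rank_sum_min,
             read_pos_rank_sum_min = read_pos_rank_sum_min,
             qual_min = qual_min, depth_min = depth_min)
  num <- unlist(th)
  if (any(!is.na(num) & !is.finite(num))) stop("thresholds must be finite")
  structure(th, class = "hard_filter_thresholds")
}

#' Apply hard filters to annotated sites
#'
#' A site fails iff any *present* annotation violates its threshold; absent
#' tags never fail. `reasons` lists every violated tag per site.
#'
#' @param x a `vcf_sites` object.
#' @param thresholds a [hard_filter_thresholds()] list.
#' @return list with `pass` (logical vector) and `reasons` (list of character
#'   vectors of violated tag names).
#' @export
hard_filter <- function(x, thresholds = hard_filter_thresholds()) {
  info <- x$info
  th <- thresholds
  viol <- function(v, bad) !is.na(v) & bad
  fails <- cbind(
    QD = viol(info$QD, info$QD < th$qd_min),
    MQ = viol(info$MQ, info$MQ < th$mq_min),
    FS = viol(info$FS, info$FS > th$fs_max),
    HaplotypeScore = viol(info$HaplotypeScore,
                          info$HaplotypeScore > th$haplotype_score_max),
    MQRankSum = viol(info$MQRankSum, info$MQRankSum < th$mq_rank_sum_min),
    ReadPosRankSum = viol(info$ReadPosRankSum,
                          info$ReadPosRankSum < th$read_pos_rank_sum_min))
  if (!is.na(th$qual_min))
    fails <- cbind(fails, QUAL = viol(x$qual, x$qual <= th$qual_min))
  if (!is.na(th$depth_min))
    fails <- cbind(fails, DP = viol(info$DP, info$DP <= th$depth_min))
  pass <- rowSums(fails) == 0
  reasons <- apply(fails, 1, function(r) colnames(fails)[r], simplify = FALSE)
  list(pass = unname(pass), reasons = reasons)
}

is_biallelic_snp <- function(x) {
  nchar(x$ref) == 1 & !grepl(",", x$alt, fixed = TRUE) & nchar(x$alt) == 1
}

#' Build the high-confidence SNP reference set
#'
#' From the combined high-coverage call set, retains sites that are biallelic
#' SNPs (single-base REF and ALT; indels excluded), pass the hard filters,
#' and satisfy QUAL > `qual_min` and combined DP > `depth_min` (both strict).
#'
#' @param x a `vcf_sites` object (jointly called high-coverage samples).
#' @param qual_min,depth_min strict retention bounds; defaults 30 and 30.
#' @param thresholds annotation thresholds, see [hard_filter_thresholds()].
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
build_high_confidence_set <- function(x, qual_min = 30, depth_min = 30,
                                      thresholds = hard_filter_thresholds()) {
  thresholds$qual_min <- qual_min
  thresholds$depth_min <- depth_min
  keep <- is_biallelic_snp(x) & hard_filter(x, thresholds)$pass
  site_key(x$chrom[keep], x$pos[keep], x$ref[keep], x$alt[keep])
}

cascade_stages <- c("hard_filter", "not_called_in_all",
                    "not_in_high_confidence", "minor_allele_carriers",
                    "multiallelic")

# Carrier count of the minor allele at each site, over called genotypes.
# Minor allele = least-frequent *observed* allele (by copy count); when only
# one allele is observed the minor allele is undetected (carriers = 0); ties
# pass only if every tied allele meets the threshold, so we return the
# minimum carrier count among the tied minor alleles.
minor_carrier_counts <- function(x) {
  n <- n_sites(x)
  out <- integer(n)
  for (i in seq_len(n)) {
    a1 <- x$gt1[i, ]
    a2 <- x$gt2[i, ]
    called <- !is.na(a1) & !is.na(a2)
    alleles <- c(a1[called], a2[called])
    if (length(alleles) == 0) { out[i] <- 0L; next }
    cnt <- table(alleles)
    if (length(cnt) < 2) { out[i] <- 0L; next }
    minor <- names(cnt)[cnt == min(cnt)]
    carriers <- vapply(minor, function(al) {
      al <- as.integer(al)
      sum((a1[called] == al) | (a2[called] == al))
    }, 0L)
    out[i] <- min(carriers)
  }
  out
}

#' Four-rule exclusion cascade on the low-coverage call set
#'
#' Applies, in fixed order: (0) hard filters with QUAL > `qual_min`
#' (default 4) and no depth bound; then excludes any remaining SNP if
#' (1) any sample genotype is missing; (2) none of its ALT alleles matches a
#' `chrom:pos:ref:alt` key of the high-confidence set; (3) the minor allele
#' is carried by fewer than `min_carriers` individuals; (4) the site is
#' multiallelic (more than one ALT allele, which covers sites biallelic for
#' two non-reference alleles). A site failing several rules is charged to the
#' first failing stage only.
#'
#' @param x a `vcf_sites` object (jointly called low-coverage samples).
#' @param hc character vector of high-confidence keys from
#'   [build_high_confidence_set()].
#' @param n_samples expected sample count; an error is raised on mismatch.
#' @param min_carriers minimum number of individuals carrying the minor
#'   allele (default 5).
#' @param qual_min strict QUAL retention bound for the low-coverage tier
#'   (default 4).
#' @param thresholds annotation thresholds, see [hard_filter_thresholds()].
#' @return list with `retained` (`vcf_sites`), `ledger` (a `filter_ledger`),
#'   and `stage` (per-input-site factor: first failing stage or "retained").
#' @export
cascade_filter <- function(x, hc, n_samples = NULL, min_carriers = 5,
                           qual_min = 4,
                           thresholds = hard_filter_thresholds()) {
  if (!is.null(n_samples) && n_samples != length(x$samples))
    stop("expected ", n_samples, " samples but VCF has ", length(x$samples))
  thresholds$qual_min <- qual_min
  thresholds$depth_min <- NA
  n <- n_sites(x)
  fail_hard <- !hard_filter(x, thresholds)$pass
  fail_missing <- rowSums(is.na(x$gt1) | is.na(x$gt2)) > 0
  alt_list <- strsplit(x$alt, ",", fixed = TRUE)
  in_hc <- vapply(seq_len(n), function(i) {
    any(site_key(x$chrom[i], x$pos[i], x$ref[i], alt_list[[i]]) %in% hc)
  }, TRUE)
  fail_carriers <- minor_carrier_counts(x) < min_carriers
  fail_multi <- lengths(alt_list) > 1
  fails <- cbind(fail_hard, fail_missing, !in_hc, fail_carriers, fail_multi)
  first <- apply(fails, 1, function(r) {
    w <- which(r)
    if (length(w)) cascade_stages[w[1]] else "retained"
  })
  stage <- factor(first, levels = c(cascade_stages, "retained"))
  ledger <- filter_ledger(stage)
  list(retained = x[stage == "retained"], ledger = ledger, stage = stage)
}

# Build a filter_ledger from the per-site first-failing-stage factor.
filter_ledger <- function(stage) {
  stopifnot(is.factor(stage))
  stages <- setdiff(levels(stage), "retained")
  excl <- as.integer(table(stage)[stages])
  n_in <- sum(table(stage))
  sites_in <- n_in - cumsum(c(0L, excl[-length(excl)]))
  structure(data.frame(stage = stages, sites_in = sites_in,
                       sites_excluded = excl, stringsAsFactors = FALSE),
            n_input = n_in,
            n_retained = as.integer(sum(stage == "retained")),
            class = c("filter_ledger", "data.frame"))
}

validate_ledger <- function(ledger) {
  n_in <- attr(ledger, "n_input")
  n_ret <- attr(ledger, "n_retained")
  if (nrow(ledger)) {
    nxt <- ledger$sites_in - ledger$sites_excluded
    if (any(nxt[-length(nxt)] != ledger$sites_in[-1]))
      stop("ledger stage accounting is inconsistent")
    if (ledger$sites_in[1] != n_in || nxt[length(nxt)] != n_ret)
      stop("ledger violates conservation: input != retained + sum(excluded)")
  } else if (n_in != n_ret) {
    stop("ledger violates conservation: input != retained + sum(excluded)")
  }
  invisible(ledger)
}

#' Render a filter ledger as a text table
#'
#' One row per stage with sites in / excluded / retained, plus a totals row.
#' Refuses (raises) if the ledger violates conservation
#' (input = retained + sum of per-stage exclusions).
#'
#' @param ledger a `filter_ledger`.
#' @return character vector of report lines, invisibly; also printed.
#' @export
ledger_report <- function(ledger) {
  validate_ledger(ledger)
  rows <- sprintf("%-24s %10d %10d %10d", ledger$stage, ledger$sites_in,
                  ledger$sites_excluded,
                  ledger$sites_in - ledger$sites_excluded)
  lines <- c(sprintf("%-24s %10s %10s %10s", "stage", "in", "excluded",
                     "retained"),
             rows,
             sprintf("%-24s %10d %10d %10d", "total",
                     attr(ledger, "n_input"),
                     as.integer(sum(ledger$sites_excluded)),
                     attr(ledger, "n_retained")))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.filter_ledger <- function(x, ...) {
  ledger_report(x)
  invisible(x)
}
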