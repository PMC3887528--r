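# VCF, region and population-table I/O, and conversion of site records to
# the dosage-matrix representation used by all downstream statistics.
#
# Internal coordinate conventions: interval files (BED) are 0-based
# half-open; VCF positions stay 1-based. Genotypes are unphased throughout;
# "/" and "|" separators are treated identically because all LD statistics
# are computed directly from genotypes, not phased haplotypes.

INFO_TAGS <- c("QD", "MQ", "FS", "HaplotypeScore", "MQRankSum",
               "ReadPosRankSum", "DP")

new_vcf_sites <- function(chrom, pos, ref, alt, qual, info, gt1, gt2, samples) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            length(qual) == n, nrow(info) == n,
            nrow(gt1) == n, nrow(gt2) == n,
            ncol(gt1) == length(samples), ncol(gt2) == length(samples))
  if (n > 0 && any(pos < 1)) stop("positions must be >= 1")
  n_alts <- lengths(strsplit(alt, ",", fixed = TRUE))
  if (n > 0 && any(n_alts < 1 | alt == "")) stop("every site needs >= 1 ALT allele")
  mx <- pmax(suppressWarnings(apply(gt1, 1, max, na.rm = TRUE)),
             suppressWarnings(apply(gt2, 1, max, na.rm = TRUE)))
  bad <- is.finite(mx) & mx > n_alts
  if (any(bad))
    stop("genotype allele index exceeds ALT count at ",
         chrom[which(bad)[1]], ":", pos[which(bad)[1]])
  dimnames(gt1) <- dimnames(gt2) <- list(NULL, as.character(samples))
  rownames(info) <- NULL
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 qual = as.numeric(qual), info = info,
                 gt1 = gt1, gt2 = gt2, samples = as.character(samples)),
            class = "vcf_sites")
}

n_sites <- function(x) length(x$pos)

#' @export
`[.vcf_sites` <- function(x, i) {
  new_vcf_sites(x$chrom[i], x$pos[i], x$ref[i], x$alt[i], x$qual[i],
                x$info[i, , drop = FALSE],
                x$gt1[i, , drop = FALSE], x$gt2[i, , drop = FALSE],
                x$samples)
}

#' @export
print.vcf_sites <- function(x, ...) {
  cat("VCF site set: ", n_sites(x), " sites, ", length(x$samples),
      " samples (", paste(utils::head(x$samples, 4), collapse = ", "),
      if (length(x$samples) > 4) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Read a multi-sample VCF into a site table
#'
#' Parses a VCF v4.x file (GT required in FORMAT) into a `vcf_sites` object
#' holding positions, alleles, QUAL, the GATK-style INFO annotations
#' (QD, MQ, FS, HaplotypeScore, MQRankSum, ReadPosRankSum, DP) and per-sample
#' diploid allele indices. Missing genotypes (`./.`) are preserved as `NA`;
#' absent INFO tags are recorded as `NA`, which downstream hard filters treat
#' as "absent, never failing" (GATK omits rank-sum tags at homozygous sites).
#'
#' @param path path to a VCF file.
#' @param samples optional character vector restricting to a sample subset;
#'   an error lists any requested samples absent from the header.
#' @return a `vcf_sites` object.
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  ln <- 0L
  found <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    ln <- ln + 1L
    if (startsWith(line, "#CHROM")) { found <- TRUE; break }
    if (!startsWith(line, "#")) break
  }
  if (!found)
    stop("malformed VCF header in '", path,
         "': no #CHROM column line found by line ", ln)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info <- as.data.frame(setNames(lapply(INFO_TAGS, function(tag) {
    raw <- vcfR::extract.info(vcf, element = tag)
    if (is.null(raw)) raw <- rep(NA_character_, n)
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "." & is.na(num)
    if (any(bad))
      stop("non-numeric value '", raw[which(bad)[1]], "' for INFO tag ", tag)
    num
  }), INFO_TAGS))
  if (ncol(vcf@gt) < 2)
    stop("VCF '", path, "' carries no sample genotype columns")
  all_samples <- colnames(vcf@gt)[-1]
  gtm <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE)
  gtm <- matrix(as.character(gtm), nrow = n,
                dimnames = list(NULL, all_samples))
  if (!is.null(samples)) {
    missing <- setdiff(samples, all_samples)
    if (length(missing))
      stop("samples not present in VCF header: ",
           paste(missing, collapse = ", "))
    gtm <- gtm[, samples, drop = FALSE]
    all_samples <- samples
  }
  parse_allele <- function(a) {
    a[a == "." | a == "" | is.na(a)] <- NA_character_
    out <- suppressWarnings(as.integer(a))
    if (any(!is.na(a) & is.na(out))) stop("malformed genotype allele index")
    out
  }
  has_sep <- grepl("[/|]", gtm)
  if (any(!has_sep & !is.na(gtm) & gtm != "."))
    stop("non-diploid genotype encountered (no '/' or '|' separator)")
  a1 <- sub("^([^/|:]*).*$", "\\1", gtm)
  a2 <- ifelse(has_sep, sub("^[^/|]*[/|]([^/|:]*).*$", "\\1", gtm),
               NA_character_)
  gt1 <- matrix(parse_allele(a1), nrow = n, dimnames = dimnames(gtm))
  gt2 <- matrix(parse_allele(a2), nrow = n, dimnames = dimnames(gtm))
  new_vcf_sites(chrom, pos, ref, alt, qual, info, gt1, gt2, all_samples)
}

#' Write a site table as a plain-text VCF
#'
#' Emits a VCF v4.2 file with GT genotypes and the numeric INFO annotations
#' held by the object. Round-trips through [read_vcf()] reproduce positions,
#' alleles, genotypes and annotation values.
#'
#' @param x a `vcf_sites` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   INFO_TAGS, INFO_TAGS),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  fmt_num <- function(v) ifelse(is.na(v), NA, formatC(v, format = "g", digits = 10))
  info_parts <- lapply(INFO_TAGS, function(tag) {
    v <- fmt_num(x$info[[tag]])
    ifelse(is.na(v), NA, paste0(tag, "=", v))
  })
  info_str <- apply(do.call(cbind, info_parts), 1, function(row) {
    row <- row[!is.na(row)]
    if (length(row) == 0) "." else paste(row, collapse = ";")
  })
  if (n_sites(x) == 0) info_str <- character(0)
  gt_str <- matrix(ifelse(is.na(x$gt1) | is.na(x$gt2), "./.",
                          paste0(x$gt1, "/", x$gt2)),
                   nrow = n_sites(x))
  qual_str <- ifelse(is.na(x$qual), ".", fmt_num(x$qual))
  body <- do.call(paste, c(list(x$chrom, x$pos, ".", x$ref, x$alt, qual_str,
                                ".", info_str, "GT"),
                           lapply(seq_along(x$samples),
                                  function(j) gt_str[, j]),
                           sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert site records to a genotype dosage matrix
#'
#' Dosage is the count of alternate alleles per sample (0/1/2, `NA` when the
#' genotype is missing). All records must be biallelic — the filtering
#' cascade removes multiallelic sites before this step — and the output is
#' sorted by (chrom, pos).
#'
#' @param x a `vcf_sites` object with biallelic records only.
#' @param populations sample-to-population assignment: a named character
#'   vector (names = samples), a two-column data frame (sample, population),
#'   or `NULL` for a single population `"pop1"`.
#' @return a `genotype_matrix` object.
#' @export
records_to_matrix <- function(x, populations = NULL) {
  if (any(grepl(",", x$alt, fixed = TRUE)))
    stop("multiallelic record at ",
         x$chrom[grepl(",", x$alt)][1], ":", x$pos[grepl(",", x$alt)][1],
         " (the filter cascade must remove multiallelic sites first)")
  key <- paste(x$chrom, x$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos): ", key[duplicated(key)][1])
  ord <- order(x$chrom, x$pos)
  dosage <- x$gt1 + x$gt2
  dosage <- dosage[ord, , drop = FALSE]
  sites <- data.frame(chrom = x$chrom[ord], pos = x$pos[ord],
                      ref = x$ref[ord], alt = x$alt[ord],
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, dosage, x$samples, populations)
}

#' Construct a genotype matrix
#'
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt`, sorted
#'   by (chrom, pos).
#' @param dosage integer matrix, sites x samples, values 0/1/2 or `NA`.
#' @param samples sample identifiers (column order of `dosage`).
#' @param populations see [records_to_matrix()].
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(sites, dosage, samples, populations = NULL) {
  stopifnot(nrow(sites) == nrow(dosage), ncol(dosage) == length(samples))
  ord <- order(sites$chrom, sites$pos)
  if (any(ord != seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  if (is.null(populations)) {
    pop <- setNames(rep("pop1", length(samples)), samples)
  } else if (is.data.frame(populations)) {
    pop <- setNames(as.character(populations[[2]]),
                    as.character(populations[[1]]))
  } else {
    pop <- populations
  }
  missing <- setdiff(samples, names(pop))
  if (length(missing))
    stop("no population label for samples: ", paste(missing, collapse = ", "))
  structure(list(sites = sites, dosage = dosage, samples = samples,
                 populations = unname(pop[samples])),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype dosage matrix: ", nrow(x$sites), " sites x ",
      length(x$samples), " samples\n", sep = "")
  tab <- table(x$populations)
  cat("Populations: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("Chromosomes: ", paste(unique(x$sites$chrom), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Subset a genotype matrix to site indices i (logical or integer).
gm_subset <- function(gm, i) {
  genotype_matrix(gm$sites[i, , drop = FALSE],
                  gm$dosage[i, , drop = FALSE],
                  gm$samples,
                  setNames(gm$populations, gm$samples))
}

#' Read a BED-like region file
#'
#' Reads 3+ column BED (chrom, start, end, optional name; 0-based half-open),
#' validates coordinates, and returns intervals normalized per region name:
#' sorted, with overlapping intervals merged.
#'
#' @param path path to a BED file.
#' @return a `region_set` data frame: `name`, `chrom`, `start`, `end`.
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(structure(data.frame(name = character(0), chrom = character(0),
                                start = numeric(0), end = numeric(0)),
                     class = c("region_set", "data.frame")))
  parts <- strsplit(lines, "\t| +")
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("line ", bad[1], ": fewer than 3 columns")
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  name <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "region", "")
  if (any(is.na(start) | is.na(end)))
    stop("line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric start/end")
  if (any(start < 0))
    stop("line ", which(start < 0)[1], ": negative start coordinate")
  if (any(start >= end))
    stop("line ", which(start >= end)[1], ": start must be < end")
  pieces <- lapply(split(data.frame(chrom, start, end,
                                    stringsAsFactors = FALSE), name),
                   merge_intervals)
  out <- do.call(rbind, Map(function(nm, d) cbind(name = nm, d),
                            names(pieces), pieces))
  rownames(out) <- NULL
  out <- out[order(out$name, out$chrom, out$start), ]
  rownames(out) <- NULL
  structure(out, class = c("region_set", "data.frame"))
}

#' Write a region set as BED
#' @param regions a `region_set` (or data frame with name/chrom/start/end).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  writeLines(paste(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   regions$name, sep = "\t"), path)
  invisible(path)
}

#' Read a two-column sample-to-population table
#'
#' @param path TSV with columns sample, population (no header, or a header
#'   line starting with `sample`).
#' @return data frame with columns `sample`, `population`.
#' @export
read_populations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  if (nrow(df) && tolower(df$sample[1]) == "sample") df <- df[-1, ]
  rownames(df) <- NULL
  df
}

#' Write a sample-to-population table
#' @param df data frame with columns `sample`, `population`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_populations <- function(df, path) {
  writeLines(paste(df$sample, df$population, sep = "\t"), path)
  invisible(path)
}
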