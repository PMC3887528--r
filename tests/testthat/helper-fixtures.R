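# In-code fixtures: small vcf_sites builders and text VCFs written at test
# time. No data files are stored.

# Build a vcf_sites object from genotype strings ("0/1", "./.", ...).
mk_sites <- function(pos, gt, chrom = "2R", ref = NULL, alt = NULL,
                     qual = NULL, info = list(), samples = NULL) {
  # genotype strings are given row-major: all samples of site 1, then site 2
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = length(pos), byrow = TRUE)
  n <- length(pos)
  ns <- ncol(gt)
  if (is.null(samples)) samples <- paste0("S", seq_len(ns))
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  if (is.null(qual)) qual <- rep(50, n)
  tags <- c("QD", "MQ", "FS", "HaplotypeScore", "MQRankSum",
            "ReadPosRankSum", "DP")
  inf <- as.data.frame(matrix(NA_real_, n, length(tags),
                              dimnames = list(NULL, tags)))
  for (tag in names(info)) inf[[tag]] <- info[[tag]]
  a1 <- suppressWarnings(matrix(as.integer(sub("[/|].*$", "", gt)), n, ns))
  a2 <- suppressWarnings(matrix(as.integer(sub("^.*[/|]", "", gt)), n, ns))
  vcfpopgen:::new_vcf_sites(rep(chrom, n), pos, ref, alt, qual, inf,
                            a1, a2, samples)
}

# Write raw VCF lines (header + body) to a temp file; returns the path.
write_vcf_text <- function(body, samples = c("S1", "S2"),
                           header = TRUE) {
  path <- tempfile(fileext = ".vcf")
  lines <- character(0)
  if (header)
    lines <- c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"))
  writeLines(c(lines, body), path)
  path
}

# Small simulation config helper with geometry scaled to a short chromosome.
small_sim_config <- function(seed, n_sites = 80, chrom_length = 20000,
                             n_per_pop = c(A = 6, B = 4), ...) {
  sim_config(seed = seed, n_sites = n_sites, chrom_length = chrom_length,
             n_per_pop = n_per_pop, inversions = list(),
             centromere = NULL, telomere = NULL, ...)
}
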