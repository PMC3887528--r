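# End-to-end pipeline: filter -> pi / density -> F_ST -> LD -> windows ->
# annotation -> coverage, driven by a YAML or list config, writing per-stage
# TSVs, the filter ledger, and a reproducible run manifest.

default_pipeline_params <- function() {
  list(bin = 1e5, step = 5e4, pi_step = 1e5, min_window_values = 100,
       min_carriers = 5, qual_low = 4, qual_hc = 30, dp_hc = 30,
       ld_max_dist = 5000, ld_bin = 10, ld_min_sep = 1000,
       ld_max_sep = 10000, flank = 5000, depth_threshold = 30)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages on a low-coverage VCF: the two-tier filter
#' cascade against the high-confidence set, per-site and windowed nucleotide
#' diversity, SNP density per chromosome, overall / per-chromosome /
#' windowed Weir-Cockerham F_ST, the LD-decay curve, windowed LD for pairs
#' 1-10 kb apart, region stratification, positional SNP classification, and
#' coverage summaries. Defaults follow the printed study parameters:
#' 100 kb windows with 50 kb step (100 kb step for pi), windows with fewer
#' than 100 values excluded, minor-allele carriers >= 5, QUAL > 30 and
#' DP > 30 for the high-confidence tier, QUAL > 4 for the low-coverage tier.
#'
#' @param config a list or path to a YAML file with elements:
#'   `inputs` (paths: `vcf`, `hc_vcf`, `populations`, optional `regions`,
#'   `gff`, `depths`), optional `chrom_lengths` (named list), optional
#'   `params` overriding the defaults above, and optional `stages`
#'   (subset of filter, pi, density, fst, ld_decay, ld_windows, regions,
#'   annotate, coverage).
#' @param out_dir output directory; created if needed.
#' @return (invisibly) list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  stages <- config$stages %||% c("filter", "pi", "density", "fst",
                                 "ld_decay", "ld_windows", "regions",
                                 "annotate", "coverage")
  inputs <- config$inputs %||% list()
  if (is.null(inputs$vcf)) stop("config validation: inputs$vcf is required")
  needed <- c(vcf = inputs$vcf)
  if ("filter" %in% stages) {
    if (is.null(inputs$hc_vcf))
      stop("config validation: filter stage requires inputs$hc_vcf")
    needed <- c(needed, hc_vcf = inputs$hc_vcf)
  }
  if ("fst" %in% stages) {
    if (is.null(inputs$populations))
      stop("config validation: fst stage requires inputs$populations")
    needed <- c(needed, populations = inputs$populations)
  }
  for (nm in c("regions", "gff", "depths"))
    if (!is.null(inputs[[nm]])) needed <- c(needed, setNames(inputs[[nm]], nm))
  absent <- needed[!file.exists(needed)]
  if (length(absent))
    stop("config validation: missing input file(s): ",
         paste(absent, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  results <- list()
  row_counts <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    rep_df <- df
    if (inherits(df, "window_stat")) {
      rep_df <- as.data.frame(df)
      rep_df$start <- rep_df$start + 1  # 1-based starts in reports
      rep_df$value <- ifelse(rep_df$excluded, NA, rep_df$value)
    }
    write_tsv(rep_df, path)
    row_counts[[name]] <<- nrow(rep_df)
    results[[name]] <<- df
  }

  low <- read_vcf(inputs$vcf)
  pops_df <- if (!is.null(inputs$populations))
    read_populations(inputs$populations) else NULL

  if ("filter" %in% stages) {
    hc_vcf <- read_vcf(inputs$hc_vcf)
    hc <- build_high_confidence_set(hc_vcf, qual_min = params$qual_hc,
                                    depth_min = params$dp_hc)
    casc <- cascade_filter(low, hc, min_carriers = params$min_carriers,
                           qual_min = params$qual_low)
    emit(as.data.frame(casc$ledger), "ledger")
    results$ledger <- casc$ledger
    retained <- casc$retained
  } else {
    retained <- low
  }
  write_vcf(retained, file.path(out_dir, "retained.vcf"))
  row_counts[["retained.vcf"]] <- n_sites(retained)

  gm <- records_to_matrix(retained, pops_df)
  chrom_lengths <- unlist(config$chrom_lengths %||%
    tapply(gm$sites$pos, gm$sites$chrom, max))
  regions <- if (!is.null(inputs$regions)) read_regions(inputs$regions)
             else NULL

  pi_df <- NULL
  if ("pi" %in% stages) {
    pi_df <- site_pi_table(gm)
    emit(pi_df, "site_pi")
    emit(windowed_pi(pi_df, chrom_lengths, bin = params$bin,
                     step = params$pi_step), "pi_windows")
  }
  if ("density" %in% stages) {
    dens <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      p <- gm$sites$pos[gm$sites$chrom == ch]
      data.frame(chrom = ch, n_snps = length(p),
                 span = unname(chrom_lengths[[ch]]),
                 bases_per_snp = snp_density(p, chrom_lengths[[ch]]))
    }))
    emit(dens, "snp_density")
  }
  comp <- NULL
  if ("fst" %in% stages) {
    comp <- wc_fst_components(gm)
    by_chrom <- do.call(rbind, lapply(names(chrom_lengths), function(ch)
      data.frame(chrom = ch,
                 fst = wc_fst_aggregate(comp[comp$chrom == ch, ]))))
    emit(rbind(by_chrom, data.frame(chrom = "overall",
                                    fst = wc_fst_aggregate(comp))),
         "fst_summary")
    emit(fst_windows(comp, chrom_lengths, bin = params$bin,
                     step = params$step,
                     min_values = params$min_window_values), "fst_windows")
  }
  if ("ld_decay" %in% stages)
    emit(ld_decay(gm, max_dist = params$ld_max_dist,
                  bin_width = params$ld_bin), "ld_decay")
  if ("ld_windows" %in% stages)
    emit(windowed_ld(gm, chrom_lengths, min_sep = params$ld_min_sep,
                     max_sep = params$ld_max_sep, bin = params$bin,
                     step = params$step,
                     min_pairs = params$min_window_values), "ld_windows")
  if ("regions" %in% stages && !is.null(regions) && nrow(regions)) {
    tags <- tag_regions(gm$sites$chrom, gm$sites$pos, regions)
    strata <- do.call(rbind, lapply(colnames(tags), function(nm) {
      inside <- tags[, nm]
      data.frame(region = nm,
                 n_snps = sum(inside),
                 mean_pi_inside = if (!is.null(pi_df))
                   mean(pi_df$pi[inside], na.rm = TRUE) else NA,
                 mean_pi_outside = if (!is.null(pi_df))
                   mean(pi_df$pi[!inside], na.rm = TRUE) else NA,
                 fst_inside = if (!is.null(comp))
                   wc_fst_aggregate(comp[inside, ]) else NA,
                 fst_outside = if (!is.null(comp))
                   wc_fst_aggregate(comp[!inside, ]) else NA)
    }))
    emit(strata, "region_strata")
  }
  if ("annotate" %in% stages && !is.null(inputs$gff)) {
    models <- read_gene_models(inputs$gff)
    cls <- classify_sites(gm$sites$chrom, gm$sites$pos, models,
                          flank = params$flank)
    emit(class_summary(cls), "snp_classes")
  }
  if ("coverage" %in% stages && !is.null(inputs$depths)) {
    depths <- utils::read.table(inputs$depths, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    cov <- depth_summary(depths, chrom_lengths,
                         threshold = params$depth_threshold)
    emit(data.frame(pct_zero = cov$pct_zero,
                    pct_ge_threshold = cov$pct_ge_threshold,
                    combined_total = cov$combined_total), "coverage_summary")
    emit(windowed_depth(depths, chrom_lengths, bin = params$bin,
                        step = params$step), "coverage_windows")
  }

  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(package = "vcfpopgen",
                   version = as.character(utils::packageVersion("vcfpopgen")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   stages = stages,
                   params = params,
                   n_input_sites = n_sites(low),
                   n_retained_sites = n_sites(retained),
                   row_counts = row_counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
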