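# Positional SNP classification against GFF3 gene models, and tagging of
# sites by named genomic regions (inversions, centromeres, telomeres).
#
# The four reported classes are coding, intronic, flank (within +/- 5 kb of
# a gene span but outside it) and intergenic, with precedence
# coding > intronic > flank > intergenic. "Within a gene" is measured from
# the gene span (transcript extent), not the CDS, matching the common
# annotator convention for upstream/downstream flanks; exonic non-CDS (UTR)
# positions are within-gene non-coding and fold into the intronic bucket.

SITE_CLASSES <- c("coding", "intronic", "flank", "intergenic")

gff_attr <- function(attributes, key) {
  m <- regmatches(attributes,
                  regexpr(paste0("(^|;)", key, "=[^;]*"), attributes))
  out <- rep(NA_character_, length(attributes))
  hit <- lengths(regmatches(attributes,
                            gregexpr(paste0("(^|;)", key, "=[^;]*"),
                                     attributes))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Read gene models from a GFF3 file
#'
#' Keeps gene spans and CDS intervals (resolving CDS -> mRNA -> gene parent
#' links); exon features are not needed for the four-class report because
#' UTRs fold into the within-gene non-coding bucket.
#'
#' @param path path to a GFF3 file.
#' @return a `gene_models` list with data frames `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`; 1-based closed) and
#'   `cds` (`chrom`, `start`, `end`, `gene_id`).
#' @export
read_gene_models <- function(path) {
  g <- ape::read.gff(path)
  g$seqid <- as.character(g$seqid)
  g$type <- as.character(g$type)
  g$strand <- as.character(g$strand)
  is_gene <- g$type %in% c("gene", "protein_coding_gene")
  genes <- data.frame(gene_id = gff_attr(g$attributes[is_gene], "ID"),
                      chrom = g$seqid[is_gene],
                      start = g$start[is_gene], end = g$end[is_gene],
                      strand = g$strand[is_gene], stringsAsFactors = FALSE)
  if (any(is.na(genes$gene_id)))
    genes$gene_id[is.na(genes$gene_id)] <-
      paste0("gene", which(is.na(genes$gene_id)))
  mrna <- g$type %in% c("mRNA", "transcript")
  mrna_parent <- setNames(gff_attr(g$attributes[mrna], "Parent"),
                          gff_attr(g$attributes[mrna], "ID"))
  is_cds <- g$type == "CDS"
  cds_parent <- gff_attr(g$attributes[is_cds], "Parent")
  # Parent may list several transcripts; first one suffices for gene lookup
  cds_parent <- sub(",.*$", "", cds_parent)
  cds_gene <- ifelse(cds_parent %in% names(mrna_parent),
                     unname(mrna_parent[cds_parent]), cds_parent)
  cds <- data.frame(chrom = g$seqid[is_cds], start = g$start[is_cds],
                    end = g$end[is_cds], gene_id = cds_gene,
                    stringsAsFactors = FALSE)
  structure(list(genes = genes, cds = cds), class = "gene_models")
}

#' Classify SNP positions by genomic context
#'
#' @param chrom,pos site coordinates (1-based).
#' @param models a `gene_models` object from [read_gene_models()].
#' @param flank flank width in bp around the gene span (default 5000).
#' @return character vector with one of `"coding"`, `"intronic"`, `"flank"`,
#'   `"intergenic"` per site. Chromosomes absent from the annotation are
#'   classified intergenic with a warning.
#' @export
classify_sites <- function(chrom, pos, models, flank = 5000) {
  out <- rep("intergenic", length(pos))
  known <- unique(c(models$genes$chrom, models$cds$chrom))
  absent <- setdiff(unique(chrom), known)
  if (length(absent))
    warning("chromosome(s) absent from annotation, classified intergenic: ",
            paste(absent, collapse = ", "))
  for (ch in intersect(unique(chrom), known)) {
    sel <- chrom == ch
    p <- pos[sel]
    cls <- rep("intergenic", length(p))
    gsp <- merge_intervals(data.frame(
      chrom = ch,
      start = models$genes$start[models$genes$chrom == ch],
      end = models$genes$end[models$genes$chrom == ch]))
    fl <- merge_intervals(data.frame(
      chrom = ch,
      start = pmax(models$genes$start[models$genes$chrom == ch] - flank, 1),
      end = models$genes$end[models$genes$chrom == ch] + flank))
    cd <- models$cds[models$cds$chrom == ch, , drop = FALSE]
    if (nrow(fl)) cls[in_intervals1(p, fl$start, fl$end)] <- "flank"
    if (nrow(gsp)) cls[in_intervals1(p, gsp$start, gsp$end)] <- "intronic"
    if (nrow(cd)) {
      cdm <- merge_intervals(cd)
      cls[in_intervals1(p, cdm$start, cdm$end)] <- "coding"
    }
    out[sel] <- cls
  }
  out
}

#' Per-class SNP counts and percentages
#'
#' @param classes character vector of site classes (see [classify_sites()]),
#'   or a `vcf_sites`/`genotype_matrix` together with `models`.
#' @param models optional `gene_models`; required when `classes` is an
#'   object rather than a precomputed class vector.
#' @param flank flank width in bp, passed through to [classify_sites()].
#' @return data frame `class`, `count`, `percent` (percentages sum to 100
#'   up to rounding); empty input gives an empty summary.
#' @export
class_summary <- function(classes, models = NULL, flank = 5000) {
  if (!is.character(classes)) {
    if (is.null(models)) stop("models required to classify sites")
    obj <- classes
    if (inherits(obj, "genotype_matrix"))
      classes <- classify_sites(obj$sites$chrom, obj$sites$pos, models, flank)
    else
      classes <- classify_sites(obj$chrom, obj$pos, models, flank)
  }
  if (length(classes) == 0)
    return(data.frame(class = character(0), count = integer(0),
                      percent = numeric(0)))
  tab <- table(factor(classes, levels = SITE_CLASSES))
  data.frame(class = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Tag sites with enclosing named regions
#'
#' @param chrom,pos site coordinates (1-based).
#' @param regions a `region_set` from [read_regions()] (0-based half-open).
#' @return logical matrix, sites x region names; `TRUE` where the site lies
#'   inside any interval of that name. A site inside overlapping regions is
#'   tagged with all of their names.
#' @export
tag_regions <- function(chrom, pos, regions) {
  nms <- unique(regions$name)
  out <- matrix(FALSE, length(pos), length(nms),
                dimnames = list(NULL, nms))
  for (nm in nms) {
    rg <- regions[regions$name == nm, , drop = FALSE]
    for (ch in unique(rg$chrom)) {
      sel <- chrom == ch
      r <- rg[rg$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      out[sel, nm] <- in_intervals0(pos[sel], r$start, r$end)
    }
  }
  out
}
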