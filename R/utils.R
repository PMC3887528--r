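# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical site key
#'
#' Builds the `chrom:pos:ref:alt` key used to match sites between call sets
#' (e.g. the low-coverage set against the high-confidence reference set).
#'
#' @param chrom,pos,ref,alt vectors describing biallelic sites.
#' @return character vector of keys.
#' @keywords internal
site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Merge overlapping intervals (0-based half-open) within each chromosome.
# Expects columns chrom, start, end; keeps any extra columns dropped.
merge_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out_chrom <- character(0)
  out_start <- numeric(0)
  out_end <- numeric(0)
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    s <- d$start
    e <- d$end
    cur_s <- s[1]
    cur_e <- e[1]
    if (length(s) > 1) {
      for (i in 2:length(s)) {
        if (s[i] < cur_e) {
          cur_e <- max(cur_e, e[i])
        } else {
          out_chrom <- c(out_chrom, ch)
          out_start <- c(out_start, cur_s)
          out_end <- c(out_end, cur_e)
          cur_s <- s[i]
          cur_e <- e[i]
        }
      }
    }
    out_chrom <- c(out_chrom, ch)
    out_start <- c(out_start, cur_s)
    out_end <- c(out_end, cur_e)
  }
  data.frame(chrom = out_chrom, start = out_start, end = out_end,
             stringsAsFactors = FALSE)
}

# Membership of 1-based positions in 0-based half-open intervals:
# pos is inside (start, end] on the 1-based scale.
# starts/ends must be sorted, non-overlapping, same chromosome.
in_intervals0 <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos - 0.5, starts)   # pos - 0.5 > start  <=>  pos > start
  idx > 0 & pos <= ends[pmax(idx, 1)]
}

# Membership of 1-based positions in 1-based closed intervals [start, end].
in_intervals1 <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, starts)
  idx > 0 & pos <= ends[pmax(idx, 1)]
}

# Write a data frame as plain TSV (pipeline report convention).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
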