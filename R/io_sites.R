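# Site-table (TSV) and BED6 output for called editing sites.

#' Write called editing sites as a TSV table
#'
#' Numeric columns are serialized with full (17 significant digit)
#' precision so that [read_site_table()] round-trips every field exactly.
#' Column documentation is written as `#`-prefixed header lines.
#'
#' @param sites `editing_sites` data frame (see [call_editing_sites()]);
#'   must be sorted by (chrom, pos).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_site_table <- function(sites, path) {
  if (nrow(sites) > 1) {
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites))))
      stopf("sites must be sorted by (chrom, pos) before writing")
  }
  df <- as.data.frame(sites)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# edcall site table",
    "# chrom/pos: 1-based genomic position of the edited base",
    "# strand: transcribed strand (+/-, * = undetermined)",
    "# ref_base/variant_base: genomic reference and variant base",
    "# edit_type: RNA-level change on the transcribed strand (e.g. C>U)",
    "# level.<sample>: per-sample variation level (mean of aligners)",
    "# aligner_level.<id>: treated-group mean variation level per aligner",
    "# p_adjusted.<id>: BH-adjusted beta-binomial p per aligner",
    "# edit_level: mean of per-aligner treated-group levels",
    "# p_value/p_adjusted: maximum over aligners (conservative)",
    "# strand_bias_p: Fisher strand-bias p (NA = test not applicable)"),
    con)
  cols <- vapply(df, is.numeric, logical(1))
  for (j in which(cols)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#'
#' @param path TSV path.
#' @return data frame of sites (numeric columns restored).
#' @export
read_site_table <- function(path) {
  hdr <- names(utils::read.delim(path, comment.char = "#", nrows = 1,
                                 check.names = FALSE))
  # base letters like "T" must not be read as logicals
  chr_cols <- c("chrom", "strand", "ref_base", "variant_base", "edit_type")
  cc <- ifelse(hdr %in% chr_cols, "character", NA)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = cc)
  if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
  num <- grepl("^(edit_level|p_value|p_adjusted|strand_bias_p|level\\.|aligner_level\\.|p_adjusted\\.)",
               names(df))
  for (j in which(num)) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Write called editing sites as BED6
#'
#' Internal 1-based inclusive positions become 0-based half-open BED
#' intervals (`pos` maps to `[pos-1, pos)`). The score column carries the
#' editing level scaled to 0-1000.
#'
#' @inheritParams write_site_table
#' @export
write_bed <- function(sites, path) {
  if (nrow(sites) > 1) {
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites))))
      stopf("sites must be sorted by (chrom, pos) before writing")
  }
  nm <- if (nrow(sites)) paste0(sites$edit_type, "_", sites$chrom, ":",
                                sites$pos) else character(0)
  df <- data.frame(
    chrom = sites$chrom,
    start = sites$pos - 1L,
    end = sites$pos,
    name = nm,
    score = round(1000 * sites$edit_level),
    strand = ifelse(sites$strand %in% c("+", "-"), sites$strand, "."),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
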