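# FASTA and transcript-table IO.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is normalized to `T`, so downstream
#' code works on a single DNA alphabet. Duplicate headers are an error.
#'
#' @param path FASTA file path.
#' @return named character vector, one element per record (possibly empty).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) return(stats::setNames(character(0), character(0)))
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stopf("duplicate FASTA header: %s", nm[duplicated(nm)][1])
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  stats::setNames(seqs, nm)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a transcript model table
#'
#' Tab-delimited with columns `transcript_id`, `chrom`, `strand`,
#' `exon_starts`, `exon_ends` (comma-separated, 1-based inclusive),
#' `cds_start`, `cds_end` (1-based inclusive genomic; `NA` for non-coding
#' transcripts).
#'
#' @param path TSV path.
#' @return data frame with list-columns `exon_starts`/`exon_ends` of integer
#'   vectors; exons are validated to be sorted and non-overlapping.
#' @export
read_transcript_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("transcript_id", "chrom", "strand", "exon_starts", "exon_ends",
           "cds_start", "cds_end")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stopf("transcript table missing column(s): %s", paste(miss, collapse = ", "))
  tab$exon_starts <- lapply(strsplit(as.character(tab$exon_starts), ","),
                            as.integer)
  tab$exon_ends <- lapply(strsplit(as.character(tab$exon_ends), ","),
                          as.integer)
  for (i in seq_len(nrow(tab))) validate_transcript(tab[i, ])
  tab
}

#' @noRd
validate_transcript <- function(tx) {
  st <- tx$exon_starts[[1]]; en <- tx$exon_ends[[1]]
  if (length(st) != length(en) || any(en < st))
    stopf("transcript %s: malformed exons", tx$transcript_id)
  if (is.unsorted(st, strictly = TRUE) || any(st[-1] <= en[-length(en)]))
    stopf("transcript %s: exons must be sorted and non-overlapping",
          tx$transcript_id)
  invisible(TRUE)
}

#' Write transcript models as the tab-delimited exon/CDS table
#'
#' @param tx data frame in the shape returned by [read_transcript_table()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_transcript_table <- function(tx, path) {
  out <- data.frame(
    transcript_id = tx$transcript_id, chrom = tx$chrom, strand = tx$strand,
    exon_starts = vapply(tx$exon_starts, paste, character(1), collapse = ","),
    exon_ends = vapply(tx$exon_ends, paste, character(1), collapse = ","),
    cds_start = tx$cds_start, cds_end = tx$cds_end,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
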