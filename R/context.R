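# Sequence-context statistics around edited cytidines: flank extraction,
# 5'-neighbor distribution, trinucleotide contexts, position frequency
# matrix, degenerate motif matching. Windows are 25-nt RNA-alphabet strings
# oriented along the transcribed strand, with the edited C at position 13
# (offset 0; offsets run -12..+12).

WINDOW_WIDTH <- 25L
WINDOW_CENTER <- 13L
RNA_BASES <- c("A", "C", "G", "U")

#' Extract the 25-nt flank window around an editing site
#'
#' The window is oriented along the transcribed strand (reverse-complemented
#' for minus-strand sites) and rendered in the RNA alphabet. Windows
#' truncated by a contig edge are an error.
#'
#' @param genome named character vector of chromosome sequences (DNA), as
#'   from [read_fasta()].
#' @param chrom,pos chromosome and 1-based position of the edited C.
#' @param strand transcribed strand, `"+"` or `"-"`.
#' @param width window width (odd; default 25).
#' @return character scalar: the RNA window with a C at its center.
#' @export
extract_window <- function(genome, chrom, pos, strand, width = WINDOW_WIDTH) {
  stopifnot(width %% 2 == 1, strand %in% c("+", "-"))
  if (!chrom %in% names(genome)) stopf("chromosome %s not in genome", chrom)
  half <- (width - 1L) %/% 2L
  if (pos - half < 1L || pos + half > nchar(genome[[chrom]]))
    stopf("window at %s:%d truncated by contig edge", chrom, pos)
  s <- substr(genome[[chrom]], pos - half, pos + half)
  w <- if (strand == "-") revcomp(s, rna = TRUE) else dna_to_rna(s)
  if (substr(w, half + 1L, half + 1L) != "C")
    stopf("window center at %s:%d (%s strand) is %s, not C",
          chrom, pos, strand, substr(w, half + 1L, half + 1L))
  w
}

#' Extract flank windows for a table of called sites
#'
#' @param sites `editing_sites` data frame (needs `chrom`, `pos`, `strand`;
#'   sites with undetermined strand are taken as plus-strand).
#' @param genome named character vector of chromosome sequences.
#' @inheritParams extract_window
#' @return character vector of windows, one per site.
#' @export
site_windows <- function(sites, genome, width = WINDOW_WIDTH) {
  vapply(seq_len(nrow(sites)), function(i)
    extract_window(genome, sites$chrom[i], sites$pos[i],
                   if (identical(sites$strand[i], "-")) "-" else "+", width),
    character(1))
}

#' @noRd
window_offset_chars <- function(windows, offset) {
  center <- (nchar(windows[1]) + 1L) %/% 2L
  substr(dna_to_rna(toupper(windows)), center + offset, center + offset)
}

#' Base distribution at a fixed offset from the edited C
#'
#' @param windows character vector of flank windows.
#' @param offset position relative to the edited C (default -1, the
#'   immediate 5' neighbor).
#' @return named integer vector of A/C/G/U counts (sums to
#'   `length(windows)`).
#' @export
neighbor_distribution <- function(windows, offset = -1) {
  stopifnot(length(windows) > 0)
  ch <- window_offset_chars(windows, offset)
  tab <- table(factor(ch, levels = RNA_BASES))
  stats::setNames(as.integer(tab), RNA_BASES)
}

#' Trinucleotide contexts (offsets -2..0) of the edited C
#'
#' DNA-alphabet input is normalized to RNA so `TCC` and `UCC` tally
#' together.
#'
#' @param windows character vector of flank windows.
#' @return named integer vector, 3-mer -> count; counts sum to the number
#'   of windows.
#' @export
trinucleotide_contexts <- function(windows) {
  stopifnot(length(windows) > 0)
  center <- (nchar(windows[1]) + 1L) %/% 2L
  tri <- substr(dna_to_rna(toupper(windows)), center - 2L, center)
  tab <- table(tri)
  stats::setNames(as.integer(tab), names(tab))
}

#' Position frequency matrix of a window set
#'
#' @param windows character vector of equal-length windows.
#' @return matrix with rows A/C/G/U and one column per offset
#'   (`-12`..`+12` for 25-nt windows); each column sums to 1.
#' @export
build_pfm <- function(windows) {
  stopifnot(length(windows) > 0)
  wlen <- nchar(windows[1])
  stopifnot(all(nchar(windows) == wlen))
  center <- (wlen + 1L) %/% 2L
  m <- do.call(rbind, strsplit(dna_to_rna(toupper(windows)), ""))
  pfm <- vapply(seq_len(wlen), function(j) {
    tab <- table(factor(m[, j], levels = RNA_BASES))
    as.numeric(tab) / length(windows)
  }, numeric(4))
  dimnames(pfm) <- list(RNA_BASES, as.character(seq_len(wlen) - center))
  pfm
}

#' Per-position information content of a position frequency matrix
#'
#' `2 - H` bits per column, where `H` is the Shannon entropy of the column;
#' ranges from 0 (uniform) to 2 (invariant base).
#'
#' @param pfm matrix from [build_pfm()].
#' @return numeric vector of bits per position.
#' @export
information_content <- function(pfm) {
  apply(pfm, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Match the degenerate editing-context motif at offsets -3..+1
#'
#' The default motif `[CGU]N[CU]C[AG]` describes the preferred context of
#' the edited C (offset 0 is the fixed C; `N` is any base). Matching is on
#' the transcript-strand RNA alphabet. Vectorized over windows.
#'
#' @param windows character vector of flank windows.
#' @param motif character-class pattern over offsets -3..+1.
#' @return logical vector.
#' @export
match_motif <- function(windows, motif = "[CGU]N[CU]C[AG]") {
  classes <- parse_motif(motif)
  ctx <- vapply(seq_along(classes), function(k)
    window_offset_chars(windows, k - 4L), character(length(windows)))
  if (length(windows) == 1) ctx <- matrix(ctx, nrow = 1)
  ok <- rep(TRUE, length(windows))
  for (k in seq_along(classes))
    ok <- ok & ctx[, k] %in% classes[[k]]
  ok
}

#' @noRd
parse_motif <- function(motif) {
  toks <- regmatches(motif, gregexpr("\\[[ACGUN]+\\]|[ACGUN]", motif))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != motif)
    stopf("malformed motif: %s", motif)
  lapply(toks, function(t) {
    t <- gsub("\\[|\\]", "", t)
    ch <- strsplit(t, "")[[1]]
    if (any(ch == "N")) RNA_BASES else ch
  })
}
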