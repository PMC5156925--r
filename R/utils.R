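# Internal sequence helpers. Sequences are plain uppercase character strings;
# DNA alphabet {A,C,G,T} internally, RNA {A,C,G,U} at the transcript-facing
# surface (flank windows, motif matching).

BASES <- c("A", "C", "G", "T")
STRANDS <- c("fwd", "rev")
COUNT_COLS <- as.vector(outer(BASES, STRANDS, paste, sep = "_"))

#' @noRd
complement_base <- function(x) chartr("ACGTU", "TGCAA", x)

#' Reverse complement of DNA or RNA strings
#'
#' Vectorized over `x`. The alphabet of the input is preserved: `U` maps to
#' `A` and, when `rna = TRUE`, complements of `A` are written as `U`.
#' @param x character vector of sequences.
#' @param rna logical; if `TRUE` the result uses the RNA alphabet.
#' @return character vector of reverse-complemented sequences.
#' @examples
#' revcomp("GGCCA")        # "TGGCC"
#' revcomp("GGCCA", rna = TRUE)  # "UGGCC"
#' @export
revcomp <- function(x, rna = FALSE) {
  out <- vapply(strsplit(chartr("ACGTU", "TGCAA", x), ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
  if (rna) chartr("T", "U", out) else out
}

#' @noRd
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @noRd
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @noRd
is_base <- function(x) x %in% BASES

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
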