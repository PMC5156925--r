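# Pileup text parsing and writing.
#
# The dialect is the classic samtools single-sample pileup: six
# whitespace-separated fields per line (chrom, 1-based position, reference
# base, depth, read-base string, phred+33 base-quality string). Mapping
# quality filtering and mate-overlap clipping are assumed done upstream by
# the aligner/pileup step; the parser only decodes and quality-filters
# base calls.

#' Parse samtools-style pileup text into strand-resolved base-call counts
#'
#' Decodes the read-base string of each pileup line into per-base,
#' per-strand call counts: `.`/`,` are reference matches on the forward /
#' reverse read direction, uppercase/lowercase letters are mismatches on the
#' forward/reverse direction. Read-start (`^` plus mapping-quality
#' character) and read-end (`$`) markers, and inserted/deleted sequence
#' after `+n`/`-n`, are consumed without counting. Deletion placeholders
#' (`*`), reference skips (`<`, `>`) and `N` calls are discarded but still
#' consume a quality character. Calls whose base quality (phred+33) is below
#' `min_base_quality` are excluded.
#'
#' @param file path to a pileup file, a connection, or a character vector of
#'   pileup lines.
#' @param min_base_quality minimum phred base quality for a call to be
#'   counted (default 20).
#' @param sample_id optional sample identifier stored in the result.
#' @return data frame with one row per position: `chrom`, `pos`, `ref`, and
#'   eight count columns `A_fwd`, `C_fwd`, `G_fwd`, `T_fwd`, `A_rev`,
#'   `C_rev`, `G_rev`, `T_rev` (plus `sample_id` when supplied).
#' @examples
#' parse_pileup("chr1 100 C 6 ..,,Tt IIIIII")
#' @export
parse_pileup <- function(file, min_base_quality = 20, sample_id = NULL) {
  lines <- if (is.character(file) && length(file) == 1L && !grepl("[\t ]", file)) {
    readLines(file)
  } else if (inherits(file, "connection")) {
    readLines(file)
  } else {
    as.character(file)
  }
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  counts <- matrix(0L, nrow = n, ncol = 8L,
                   dimnames = list(NULL, COUNT_COLS))
  chrom <- character(n); pos <- integer(n); ref <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], "[\t ]+")[[1]]
    if (length(f) != 6L)
      stopf("pileup parse error at line %d: expected 6 fields, found %d",
            i, length(f))
    chrom[i] <- f[1]
    pos[i] <- as.integer(f[2])
    rb <- toupper(f[3])
    ref[i] <- rb
    counts[i, ] <- decode_pileup_bases(f[5], f[6], rb, min_base_quality, i)
  }
  out <- data.frame(chrom = chrom, pos = pos, ref = ref,
                    counts, stringsAsFactors = FALSE)
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

# Decode one read-base string against its quality string; returns the eight
# (base, strand) counts. `line_no` only feeds error messages.
#' @noRd
decode_pileup_bases <- function(bases, quals, ref_base, min_base_quality,
                                line_no = NA_integer_) {
  s <- gsub("\\^.", "", bases)   # read starts carry a mapping-quality char
  s <- gsub("\\$", "", s, fixed = FALSE)
  # strip indel segments: sign, length, then that many sequence characters
  repeat {
    m <- regexpr("[+-][0-9]+", s)
    if (m == -1L) break
    len <- as.integer(substr(s, m + 1L, m + attr(m, "match.length") - 1L))
    s <- paste0(substr(s, 1L, m - 1L),
                substr(s, m + attr(m, "match.length") + len, nchar(s)))
  }
  ch <- strsplit(s, "")[[1]]
  qv <- utf8ToInt(quals) - 33L
  if (length(ch) != length(qv))
    stopf(paste0("pileup parse error at line %s: base string (%d calls after ",
                 "marker removal) does not match quality string (%d)"),
          line_no, length(ch), length(qv))
  keep <- qv >= min_base_quality
  ch <- ch[keep]
  out <- integer(8L); names(out) <- COUNT_COLS
  if (!length(ch)) return(out)
  base <- ifelse(ch == ".", ref_base,
          ifelse(ch == ",", ref_base, toupper(ch)))
  # letters: uppercase = fwd, lowercase = rev; '.'=fwd, ','=rev
  strand <- ifelse(ch == ".", "fwd",
            ifelse(ch == ",", "rev",
            ifelse(ch == toupper(ch), "fwd", "rev")))
  ok <- base %in% BASES
  tb <- table(factor(paste(base[ok], strand[ok], sep = "_"),
                     levels = COUNT_COLS))
  out[names(tb)] <- as.integer(tb)
  out
}

#' Write base-call profiles as samtools-style pileup text
#'
#' The inverse of [parse_pileup()] for quality-passing calls: each position's
#' counts are expanded into a read-base string (reference matches first as
#' `.`/`,`, then variant bases in `A`,`C`,`G`,`T` order, forward before
#' reverse) with a constant high base quality, so that parsing the output
#' recovers the counts exactly.
#'
#' @param profile data frame as returned by [parse_pileup()] (one sample).
#' @param file path to write to.
#' @param qual_char quality character used for every call (default `"I"`,
#'   phred 40).
#' @return invisibly, the file path.
#' @export
write_pileup <- function(profile, file, qual_char = "I") {
  n <- nrow(profile)
  lines <- character(n)
  for (i in seq_len(n)) {
    rb <- profile$ref[i]
    parts <- character(0)
    for (b in BASES) for (st in STRANDS) {
      k <- profile[[paste(b, st, sep = "_")]][i]
      if (k == 0L) next
      sym <- if (b == rb) {
        if (st == "fwd") "." else ","
      } else {
        if (st == "fwd") b else tolower(b)
      }
      parts <- c(parts, strrep(sym, k))
    }
    bases <- paste(parts, collapse = "")
    depth <- nchar(bases)
    lines[i] <- paste(profile$chrom[i], profile$pos[i], rb, depth,
                      if (depth) bases else "*",
                      if (depth) strrep(qual_char, depth) else "*",
                      sep = "\t")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Combine per-sample base-call profiles into one long table
#'
#' Positions absent from a sample (no coverage) are filled with zero counts
#' so that every sample covers the union of positions.
#'
#' @param profiles named list of per-sample profile data frames
#'   ([parse_pileup()] output); names are the sample identifiers.
#' @return long data frame with a `sample_id` column and one row per
#'   (position, sample).
#' @export
merge_profiles <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  key <- unique(do.call(rbind, lapply(profiles, function(p)
    p[, c("chrom", "pos", "ref")])))
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  out <- do.call(rbind, lapply(names(profiles), function(sid) {
    p <- profiles[[sid]]
    idx <- match(paste(key$chrom, key$pos), paste(p$chrom, p$pos))
    cnt <- matrix(0L, nrow(key), 8L, dimnames = list(NULL, COUNT_COLS))
    hit <- !is.na(idx)
    cnt[hit, ] <- as.matrix(p[idx[hit], COUNT_COLS])
    data.frame(chrom = key$chrom, pos = key$pos, ref = key$ref,
               sample_id = sid, cnt, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
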