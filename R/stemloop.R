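# Inverted-repeat / stem-loop detection in the 25-nt flank window. Arms are
# strict reverse complements (no G.U wobble); an optional "interrupted"
# mode tolerates one unpaired nucleotide inside an arm.

#' @noRd
new_stemloop_call <- function(arm_length = 0L, left_span = c(NA_integer_, NA_integer_),
                              right_span = c(NA_integer_, NA_integer_),
                              loop_length = NA_integer_, interrupted = FALSE,
                              arm_sequence = "") {
  structure(list(arm_length = as.integer(arm_length),
                 left_span = as.integer(left_span),
                 right_span = as.integer(right_span),
                 loop_length = as.integer(loop_length),
                 interrupted = interrupted,
                 arm_sequence = arm_sequence),
            class = "stemloop_call")
}

#' @export
print.stemloop_call <- function(x, ...) {
  if (x$arm_length == 0) {
    cat("stemloop_call: no inverted repeat found\n")
  } else {
    cat(sprintf("stemloop_call: arm %d nt (%s)%s, loop %d nt, left %d-%d, right %d-%d\n",
                x$arm_length, x$arm_sequence,
                if (x$interrupted) " interrupted" else "",
                x$loop_length, x$left_span[1], x$left_span[2],
                x$right_span[1], x$right_span[2]))
  }
  invisible(x)
}

#' Find the maximal inverted repeat flanking the central edited C
#'
#' Exhaustive search over all (left substring, right substring) pairs with
#' the left arm entirely 5' of the center and the right arm entirely 3' of
#' it, where the right arm is the reverse complement of the left, and arm
#' length lies in `[min_arm, max_arm]`. Returns the maximal arm length;
#' ties are broken by smallest loop (nucleotides strictly between the
#' arms), then by the left arm ending closest to the center, then by the
#' leftmost right arm.
#'
#' @param window flank window (RNA or DNA alphabet, odd length, C at the
#'   center).
#' @param min_arm,max_arm allowed arm-length range (defaults 3 and 10).
#' @return `stemloop_call` with `arm_length = 0` when no pair exists.
#' @examples
#' find_inverted_repeat("ACACGGCCAUUCCUGGCCACACACA")  # arm 5, loop 4
#' @export
find_inverted_repeat <- function(window, min_arm = 3, max_arm = 10) {
  w <- dna_to_rna(toupper(window))
  L <- nchar(w)
  center <- (L + 1L) %/% 2L
  for (k in seq(min(max_arm, center - 1L), min_arm)) {
    best <- NULL
    for (i in seq_len(center - k)) {        # left arm i..i+k-1, ends < center
      left <- substr(w, i, i + k - 1L)
      rc <- revcomp(left, rna = TRUE)
      for (j in seq(center + 1L, L - k + 1L)) {  # right arm starts > center
        if (substr(w, j, j + k - 1L) != rc) next
        cand <- list(loop = j - i - k, left_end = i + k - 1L, i = i, j = j)
        if (is.null(best) ||
            cand$loop < best$loop ||
            (cand$loop == best$loop && cand$left_end > best$left_end) ||
            (cand$loop == best$loop && cand$left_end == best$left_end &&
             cand$j < best$j))
          best <- cand
      }
    }
    if (!is.null(best))
      return(new_stemloop_call(k, c(best$i, best$left_end),
                               c(best$j, best$j + k - 1L),
                               best$loop, FALSE,
                               substr(w, best$i, best$left_end)))
  }
  new_stemloop_call()
}

# Does `right` equal revcomp(`left`) once one internal nucleotide of the
# longer arm is left unpaired? Both must differ in length by exactly 1.
#' @noRd
match_with_bulge <- function(left, right) {
  if (nchar(left) == nchar(right) + 1L) {
    long <- left; target <- revcomp(right, rna = TRUE)
  } else if (nchar(right) == nchar(left) + 1L) {
    long <- right; target <- revcomp(left, rna = TRUE)
  } else return(FALSE)
  n <- nchar(long)
  for (d in 2:(n - 1L)) {  # unpaired nt strictly inside the arm
    if (paste0(substr(long, 1L, d - 1L), substr(long, d + 1L, n)) == target)
      return(TRUE)
  }
  FALSE
}

#' Call the stem-loop model with the edited C at the loop's 3' end
#'
#' A constrained variant of [find_inverted_repeat()]: the right arm must
#' begin immediately 3' of the central C, and the loop (the unpaired
#' stretch ending at the C) may be at most `max_loop` nt. One unpaired
#' nucleotide inside an arm is tolerated and flagged `interrupted`;
#' uninterrupted pairings are preferred at equal arm length. The arm-length
#' floor is 2, the smallest flanking palindrome observed for verified
#' sites.
#'
#' @inheritParams find_inverted_repeat
#' @param max_loop maximum loop length (default 7).
#' @param allow_interruption tolerate one unpaired nucleotide inside an arm
#'   (default `TRUE`).
#' @return `stemloop_call` (`arm_length = 0` = no call); `loop_length`
#'   counts the unpaired nucleotides ending at (and including) the C.
#' @examples
#' call_loop_model("ACACGGCCAUUCCUGGCCACACACA")  # loop 4, arm 5
#' @export
call_loop_model <- function(window, max_loop = 7, min_arm = 2, max_arm = 10,
                            allow_interruption = TRUE) {
  w <- dna_to_rna(toupper(window))
  L <- nchar(w)
  center <- (L + 1L) %/% 2L
  cands <- list()
  for (lp in seq_len(min(max_loop, center - 1L))) {
    left_end <- center - lp
    for (k in seq(min_arm, max_arm)) {
      if (center + k > L) break
      right <- substr(w, center + 1L, center + k)
      # strict arms of length k
      if (left_end - k + 1L >= 1L) {
        left <- substr(w, left_end - k + 1L, left_end)
        if (right == revcomp(left, rna = TRUE))
          cands[[length(cands) + 1L]] <-
            list(arm = k, loop = lp, interrupted = FALSE,
                 left = c(left_end - k + 1L, left_end),
                 right = c(center + 1L, center + k), seq = left)
      }
      if (!allow_interruption) next
      # interrupted: one unpaired nt inside either arm
      if (left_end - k >= 1L) {
        left1 <- substr(w, left_end - k, left_end)  # k+1 nt, one bulged
        if (match_with_bulge(left1, right))
          cands[[length(cands) + 1L]] <-
            list(arm = k, loop = lp, interrupted = TRUE,
                 left = c(left_end - k, left_end),
                 right = c(center + 1L, center + k), seq = left1)
      }
      if (center + k + 1L <= L && left_end - k + 1L >= 1L) {
        right1 <- substr(w, center + 1L, center + k + 1L)
        left0 <- substr(w, left_end - k + 1L, left_end)
        if (match_with_bulge(left0, right1))
          cands[[length(cands) + 1L]] <-
            list(arm = k, loop = lp, interrupted = TRUE,
                 left = c(left_end - k + 1L, left_end),
                 right = c(center + 1L, center + k + 1L), seq = left0)
      }
    }
  }
  if (!length(cands)) return(new_stemloop_call())
  # prefer longest arm, then uninterrupted, then smallest loop
  ord <- order(-vapply(cands, `[[`, numeric(1), "arm"),
               vapply(cands, `[[`, logical(1), "interrupted"),
               vapply(cands, `[[`, numeric(1), "loop"))
  best <- cands[[ord[1]]]
  new_stemloop_call(best$arm, best$left, best$right, best$loop,
                    best$interrupted, best$seq)
}

#' Fraction of random C-centered windows with a flanking inverted repeat
#'
#' Samples `n` windows of `width` nt centered on a C uniformly (with
#' replacement) over all eligible positions of a transcriptome, and returns
#' the fraction carrying a flanking inverted repeat of at least `min_arm`
#' nt (per [find_inverted_repeat()] with arms up to `max_arm`).
#'
#' @param transcriptome named character vector of transcript sequences, as
#'   from [read_fasta()].
#' @param n number of windows to sample.
#' @param seed RNG seed (sampling is reproducible given the seed).
#' @param min_arm minimum arm length counted as a repeat (default 4).
#' @param max_arm maximum arm length searched (default 10).
#' @param width window width (default 25).
#' @return fraction in `[0, 1]`.
#' @export
background_repeat_fraction <- function(transcriptome, n, seed, min_arm = 4,
                                       max_arm = 10, width = WINDOW_WIDTH) {
  stopifnot(length(transcriptome) > 0, n > 0)
  half <- (width - 1L) %/% 2L
  elig <- do.call(rbind, lapply(seq_along(transcriptome), function(si) {
    s <- chartr("Uu", "Tt", toupper(transcriptome[[si]]))
    p <- gregexpr("C", s, fixed = TRUE)[[1]]
    p <- p[p != -1 & p - half >= 1 & p + half <= nchar(s)]
    if (!length(p)) return(NULL)
    cbind(si, p)
  }))
  if (is.null(elig) || !nrow(elig))
    stopf("no eligible C-centered window of width %d in the transcriptome", width)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pick <- elig[sample.int(nrow(elig), n, replace = TRUE), , drop = FALSE]
  hits <- vapply(seq_len(n), function(i) {
    s <- transcriptome[[pick[i, 1]]]
    w <- substr(s, pick[i, 2] - half, pick[i, 2] + half)
    find_inverted_repeat(w, min_arm = min_arm, max_arm = max_arm)$arm_length >= min_arm
  }, logical(1))
  mean(hits)
}

#' Histogram of inverted-repeat arm lengths
#'
#' @param calls list of `stemloop_call` objects (or a data frame with an
#'   `arm_length` column).
#' @return named integer vector, arm length -> count; counts sum to the
#'   number of calls (arm length 0 = no repeat found).
#' @export
repeat_length_histogram <- function(calls) {
  arms <- if (is.data.frame(calls)) calls$arm_length
          else vapply(calls, function(x) x$arm_length, integer(1))
  tab <- table(arms)
  stats::setNames(as.integer(tab), names(tab))
}
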