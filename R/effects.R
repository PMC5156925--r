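# Gene-feature and codon-consequence classification of editing sites given
# transcript models (exon/CDS table) and the genome sequence.

FEATURE_PRIORITY <- c("CDS" = 1, "5'UTR" = 2, "3'UTR" = 2, "ncRNA" = 3,
                      "intronic" = 4, "unknown" = 5)

#' Classify one editing site by gene feature and codon consequence
#'
#' Feature is assigned by interval arithmetic against the transcript
#' models: CDS exon, 5'/3' UTR, non-coding RNA exon, intron, untranscribed
#' (within `flank` nt of a transcript boundary), or intergenic. When the
#' site falls in a CDS, the affected codon is translated before and after
#' the edit with the standard genetic code and the consequence reported as
#' synonymous, missense, nonsense (new stop) or stop-loss, together with
#' HGVS-flavored `c.` (cDNA) and `p.` (protein, single-letter, `X` = stop)
#' change strings. When several transcripts overlap the site, the reported
#' model is chosen by feature priority (CDS > UTR > ncRNA > intron), then
#' lexicographic transcript id; all overlapping transcripts are listed.
#'
#' @param site one-row data frame (or list) with `chrom`, `pos`,
#'   `ref_base`, `variant_base` -- genomic-strand bases.
#' @param transcripts transcript table (see [read_transcript_table()]).
#' @param genome named character vector of chromosome sequences.
#' @param flank untranscribed-flank width in nt (default 1000).
#' @return data frame of class `effect_call` with columns `feature`,
#'   `consequence`, `transcript_id`, `cdna_change`, `protein_change`,
#'   `overlapping` (comma-separated transcript ids).
#' @export
classify_site <- function(site, transcripts, genome, flank = 1000) {
  chrom <- site$chrom; pos <- site$pos
  cand <- transcripts[transcripts$chrom == chrom, , drop = FALSE]
  res <- list()
  near <- FALSE
  for (i in seq_len(nrow(cand))) {
    tx <- cand[i, ]
    span <- c(min(tx$exon_starts[[1]]), max(tx$exon_ends[[1]]))
    if (pos < span[1] - flank || pos > span[2] + flank) next
    if (pos < span[1] || pos > span[2]) { near <- TRUE; next }
    res[[length(res) + 1L]] <- classify_in_transcript(site, tx, genome)
  }
  if (!length(res)) {
    feature <- if (near) "untranscribed" else "intergenic"
    return(effect_row(feature, NA_character_, NA_character_,
                      NA_character_, NA_character_, ""))
  }
  ord <- order(vapply(res, function(r) FEATURE_PRIORITY[[r$feature]], numeric(1)),
               vapply(res, function(r) r$transcript_id, character(1)))
  best <- res[[ord[1]]]
  best$overlapping <- paste(sort(vapply(res, function(r) r$transcript_id,
                                        character(1))), collapse = ",")
  class(best) <- c("effect_call", "data.frame")
  best
}

#' @noRd
effect_row <- function(feature, consequence, transcript_id, cdna, prot,
                       overlapping) {
  structure(data.frame(feature = feature, consequence = consequence,
                       transcript_id = transcript_id, cdna_change = cdna,
                       protein_change = prot, overlapping = overlapping,
                       stringsAsFactors = FALSE),
            class = c("effect_call", "data.frame"))
}

# Classify within one transcript model (site known to lie in its span).
#' @noRd
classify_in_transcript <- function(site, tx, genome) {
  pos <- site$pos
  st <- tx$exon_starts[[1]]; en <- tx$exon_ends[[1]]
  in_exon <- any(pos >= st & pos <= en)
  coding <- !is.na(tx$cds_start) && !is.na(tx$cds_end)
  if (!in_exon) {
    return(effect_row(if (coding) "intronic" else "intronic",
                      NA_character_, tx$transcript_id,
                      NA_character_, NA_character_, ""))
  }
  if (!coding)
    return(effect_row("ncRNA", NA_character_, tx$transcript_id,
                      NA_character_, NA_character_, ""))
  if (pos < tx$cds_start || pos > tx$cds_end) {
    # genomic side before the CDS is 5' on plus-strand transcripts, 3' on minus
    upstream <- pos < tx$cds_start
    feature <- if ((upstream && tx$strand == "+") || (!upstream && tx$strand == "-"))
      "5'UTR" else "3'UTR"
    return(effect_row(feature, NA_character_, tx$transcript_id,
                      NA_character_, NA_character_, ""))
  }
  codon_consequence(site, tx, genome)
}

# Consequence of the edit within the CDS of `tx`.
#' @noRd
codon_consequence <- function(site, tx, genome) {
  st <- tx$exon_starts[[1]]; en <- tx$exon_ends[[1]]
  cds_ex_st <- pmax(st, tx$cds_start); cds_ex_en <- pmin(en, tx$cds_end)
  keep <- cds_ex_st <= cds_ex_en
  cds_ex_st <- cds_ex_st[keep]; cds_ex_en <- cds_ex_en[keep]
  gpos <- unlist(lapply(seq_along(cds_ex_st), function(i)
    seq(cds_ex_st[i], cds_ex_en[i])))
  gseq <- strsplit(paste0(substring(genome[[tx$chrom]], cds_ex_st, cds_ex_en),
                          collapse = ""), "")[[1]]
  if (tx$strand == "-") {
    gpos <- rev(gpos)
    gseq <- rev(strsplit(complement_base(paste(gseq, collapse = "")), "")[[1]])
  }
  if (length(gseq) %% 3 != 0) {
    warnf("transcript %s: CDS length %d not divisible by 3; model rejected",
          tx$transcript_id, length(gseq))
    return(effect_row("unknown", NA_character_, tx$transcript_id,
                      NA_character_, NA_character_, ""))
  }
  off <- match(site$pos, gpos)            # 1-based position in the CDS
  ref_tx <- if (tx$strand == "-") complement_base(site$ref_base) else site$ref_base
  var_tx <- if (tx$strand == "-") complement_base(site$variant_base) else site$variant_base
  if (gseq[off] != ref_tx)
    warnf("transcript %s: reference base mismatch at cDNA position %d",
          tx$transcript_id, off)
  codon_i <- (off - 1L) %/% 3L            # 0-based codon index
  within <- (off - 1L) %% 3L              # 0-based position within codon
  old_codon <- paste(gseq[codon_i * 3L + 1:3], collapse = "")
  new_seq <- gseq; new_seq[off] <- var_tx
  new_codon <- paste(new_seq[codon_i * 3L + 1:3], collapse = "")
  gc <- Biostrings::GENETIC_CODE
  old_aa <- unname(gc[old_codon]); new_aa <- unname(gc[new_codon])
  consequence <- if (old_aa == new_aa) "synonymous"
    else if (new_aa == "*" && old_aa != "*") "nonsense"
    else if (old_aa == "*" && new_aa != "*") "stop-loss"
    else "missense"
  aa1 <- function(a) if (a == "*") "X" else a
  effect_row("CDS", consequence, tx$transcript_id,
             sprintf("c.%s%d%s", ref_tx, off, var_tx),
             sprintf("p.%s%d%s", aa1(old_aa), codon_i + 1L, aa1(new_aa)),
             "")
}

#' Classify a whole table of sites
#'
#' @param sites `editing_sites` data frame.
#' @inheritParams classify_site
#' @return data frame with one effect row per site, prefixed by `chrom` and
#'   `pos`.
#' @export
classify_sites <- function(sites, transcripts, genome, flank = 1000) {
  rows <- lapply(seq_len(nrow(sites)), function(i)
    classify_site(sites[i, ], transcripts, genome, flank))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  cbind(sites[, c("chrom", "pos")], out)
}

#' Tally effect calls into a feature / consequence count table
#'
#' @param effects data frame from [classify_sites()] (needs `feature` and
#'   `consequence` columns).
#' @return data frame with columns `feature`, `consequence`, `n`; the `n`
#'   column sums to the number of classified sites.
#' @export
feature_tally <- function(effects) {
  if (!nrow(effects))
    return(data.frame(feature = character(0), consequence = character(0),
                      n = integer(0)))
  key <- paste(effects$feature,
               ifelse(is.na(effects$consequence), "", effects$consequence),
               sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r")
  data.frame(
    feature = vapply(parts, `[`, character(1), 1),
    consequence = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                         character(1)),
    n = as.integer(tab), stringsAsFactors = FALSE)
}
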