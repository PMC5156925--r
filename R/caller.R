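# The step-wise filter cascade that turns two-group, two-aligner base-call
# profiles into called RNA editing sites.

#' Call C-to-U (and other) RNA editing sites from dual-aligner profiles
#'
#' Applies the full cascade per aligner dataset -- (1) depth gate, (2)
#' candidate-variant gate, (3) other-base contamination gate, (4)
#' range-over-mean dispersion gate, (5) beta-binomial group test with
#' Benjamini-Hochberg correction, (6) group-specificity gate (control mean
#' level exactly 0, treated mean at least `min_treated_mean_level`) -- then
#' requires (7) concordance of the surviving positions in every aligner
#' dataset, (8) the treated-group strand-bias gate, and (9) a final mean
#' editing level above `final_min_edit_level`. The editing level of a site
#' is the mean over aligners of the treated-group mean variation level.
#'
#' @param profiles_by_aligner named list (one element per aligner) of long
#'   profile data frames as returned by [merge_profiles()] or
#'   [simulate_dataset()].
#' @param samples sample sheet data frame with columns `sample_id` and
#'   `group` (`"control"` / `"treated"`).
#' @param thresholds [filter_thresholds()] record.
#' @param transcripts optional transcript table (see
#'   [read_transcript_table()]) used as a fallback to assign the transcribed
#'   strand when read directionality is uninformative.
#' @param strand_agreement fraction of read calls that must share a
#'   direction before that direction is taken as the transcribed strand
#'   (default 0.9).
#' @return data frame of class `editing_sites`, sorted by (chrom, pos), with
#'   per-sample levels (`level.<sample>`), per-aligner treated means
#'   (`aligner_level.<id>`) and adjusted p-values (`p_adjusted.<id>`), the
#'   combined `edit_level`, conservative `p_value`/`p_adjusted` (maximum over
#'   aligners), and `strand_bias_p`. Attribute `gate_summary` holds the
#'   step-wise survivor table; attribute `trace` the per-position gate
#'   decisions per aligner.
#' @export
call_editing_sites <- function(profiles_by_aligner, samples,
                               thresholds = filter_thresholds(),
                               transcripts = NULL,
                               strand_agreement = 0.9) {
  stopifnot(is.list(profiles_by_aligner), !is.null(names(profiles_by_aligner)))
  aligners <- names(profiles_by_aligner)
  if (length(aligners) != 2)
    warnf("expected 2 aligner datasets, got %d; concordance will require all of them",
          length(aligners))
  samples$group <- as.character(samples$group)
  if (!all(samples$group %in% c("control", "treated")))
    stopf("sample sheet group must be 'control' or 'treated'")
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample_id in sample sheet")
  if (!all(c("control", "treated") %in% samples$group))
    stopf("sample sheet needs at least one control and one treated sample")
  for (al in aligners) {
    extra <- setdiff(unique(profiles_by_aligner[[al]]$sample_id),
                     samples$sample_id)
    if (length(extra))
      stopf("sample(s) in %s profiles but not in sample sheet: %s",
            al, paste(extra, collapse = ", "))
  }

  per_aligner <- lapply(aligners, function(al)
    evaluate_aligner(profiles_by_aligner[[al]], samples, thresholds))
  names(per_aligner) <- aligners

  # concordance: same position and same variant base surviving gates 1-6
  # independently in every aligner dataset
  keys <- lapply(per_aligner, function(ev) {
    with(ev$positions, paste(chrom, pos, variant_base)[pass16])
  })
  common <- Reduce(intersect, keys)
  gate_rows <- lapply(per_aligner, function(ev)
    match(common, with(ev$positions, paste(chrom, pos, variant_base))))

  n_common <- length(common)
  strand_p <- rep(NA_real_, n_common)
  strand_ok <- rep(TRUE, n_common)
  if (n_common) {
    for (j in seq_len(n_common)) {
      for (al in aligners) {
        row <- per_aligner[[al]]$positions[gate_rows[[al]][j], ]
        sb <- strand_bias_gate(c(ref_fwd = row$t_ref_fwd, ref_rev = row$t_ref_rev,
                                 var_fwd = row$t_var_fwd, var_rev = row$t_var_rev),
                               thresholds)
        if (sb$status == "fail") strand_ok[j] <- FALSE
        if (!is.na(sb$p))
          strand_p[j] <- min(strand_p[j], sb$p, na.rm = TRUE)
      }
    }
  }

  # per-aligner treated means and final level
  al_mean_mat <- vapply(aligners, function(al)
    per_aligner[[al]]$positions$treated_mean[gate_rows[[al]]],
    numeric(n_common))
  al_padj_mat <- vapply(aligners, function(al)
    per_aligner[[al]]$positions$p_adj[gate_rows[[al]]],
    numeric(n_common))
  al_p_mat <- vapply(aligners, function(al)
    per_aligner[[al]]$positions$p_raw[gate_rows[[al]]],
    numeric(n_common))
  if (n_common == 1) {
    al_mean_mat <- matrix(al_mean_mat, 1, dimnames = list(NULL, aligners))
    al_padj_mat <- matrix(al_padj_mat, 1, dimnames = list(NULL, aligners))
    al_p_mat <- matrix(al_p_mat, 1, dimnames = list(NULL, aligners))
  }
  edit_level <- if (n_common) rowMeans(al_mean_mat) else numeric(0)
  final_ok <- edit_level > thresholds$final_min_edit_level

  keep <- strand_ok & final_ok
  ref_al <- aligners[1]
  base_rows <- gate_rows[[ref_al]][keep]
  pos_tab <- per_aligner[[ref_al]]$positions[base_rows, , drop = FALSE]

  # per-sample levels averaged over aligners
  sample_ids <- samples$sample_id
  lev_mat <- matrix(0, sum(keep), length(sample_ids),
                    dimnames = list(NULL, sample_ids))
  for (al in aligners) {
    lv <- per_aligner[[al]]$levels[gate_rows[[al]][keep], , drop = FALSE]
    lev_mat <- lev_mat + lv[, sample_ids, drop = FALSE] / length(aligners)
  }

  # transcribed strand from read directionality, else transcript models
  fwd_frac <- pos_tab$fwd_frac
  strand <- rep("*", nrow(pos_tab))
  strand[fwd_frac >= strand_agreement] <- "+"
  strand[fwd_frac <= 1 - strand_agreement] <- "-"
  if (!is.null(transcripts) && any(strand == "*")) {
    for (i in which(strand == "*")) {
      st <- transcript_strand_at(transcripts, pos_tab$chrom[i], pos_tab$pos[i])
      if (!is.na(st)) strand[i] <- st
    }
  }
  edit_type <- ifelse(strand %in% c("+", "-"),
                      assign_edit_type(pos_tab$ref, pos_tab$variant_base, strand),
                      paste0(pos_tab$ref, ">", pos_tab$variant_base))

  sites <- data.frame(
    chrom = pos_tab$chrom, pos = pos_tab$pos, strand = strand,
    ref_base = pos_tab$ref, variant_base = pos_tab$variant_base,
    edit_type = edit_type,
    edit_level = edit_level[keep],
    p_value = if (sum(keep)) apply(al_p_mat[keep, , drop = FALSE], 1, max) else numeric(0),
    p_adjusted = if (sum(keep)) apply(al_padj_mat[keep, , drop = FALSE], 1, max) else numeric(0),
    strand_bias_p = strand_p[keep],
    stringsAsFactors = FALSE)
  for (sid in sample_ids) sites[[paste0("level.", sid)]] <- lev_mat[, sid]
  for (al in aligners) {
    sites[[paste0("aligner_level.", al)]] <- al_mean_mat[keep, al]
    sites[[paste0("p_adjusted.", al)]] <- al_padj_mat[keep, al]
  }
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL

  gate_summary <- build_gate_summary(per_aligner, n_common,
                                     sum(strand_ok), sum(keep))
  structure(sites,
            class = c("editing_sites", "data.frame"),
            gate_summary = gate_summary,
            thresholds = thresholds,
            trace = lapply(per_aligner, function(ev)
              ev$positions[, c("chrom", "pos", "variant_base",
                               grep("^gate", names(ev$positions), value = TRUE)),
                           drop = FALSE]))
}

# Evaluate gates 1-6 for one aligner dataset. Returns list(positions =
# per-position data frame with gate booleans and statistics, levels =
# per-sample variation-level matrix).
#' @noRd
evaluate_aligner <- function(profile, samples, th) {
  sample_ids <- samples$sample_id
  is_treated <- samples$group == "treated"
  upos <- unique(profile[, c("chrom", "pos", "ref")])
  upos <- upos[order(upos$chrom, upos$pos), , drop = FALSE]
  rownames(upos) <- NULL
  nP <- nrow(upos); nS <- length(sample_ids)
  key <- paste(profile$chrom, profile$pos)
  ri <- match(key, paste(upos$chrom, upos$pos))
  ci <- match(profile$sample_id, sample_ids)
  cnt <- lapply(COUNT_COLS, function(cc) {
    M <- matrix(0L, nP, nS, dimnames = list(NULL, sample_ids))
    M[cbind(ri, ci)] <- profile[[cc]]
    M
  })
  names(cnt) <- COUNT_COLS
  base_tot <- lapply(BASES, function(b)
    cnt[[paste0(b, "_fwd")]] + cnt[[paste0(b, "_rev")]])
  names(base_tot) <- BASES
  depth <- Reduce(`+`, base_tot)
  fwd_tot <- Reduce(`+`, cnt[paste0(BASES, "_fwd")])

  ref_idx <- match(upos$ref, BASES)
  pick_ref <- function(mats) {
    out <- matrix(0L, nP, nS)
    for (b in seq_along(BASES)) {
      rows <- which(ref_idx == b)
      out[rows, ] <- mats[[b]][rows, , drop = FALSE]
    }
    out
  }
  ref_cnt <- pick_ref(base_tot)

  # gate 1: per-sample depth and group mean depth
  gate1 <- rowSums(depth >= th$min_calls_per_sample) == nS &
    rowMeans(depth[, !is_treated, drop = FALSE]) >= th$min_group_mean_depth &
    rowMeans(depth[, is_treated, drop = FALSE]) >= th$min_group_mean_depth

  # gate 2: candidate variant base. A base qualifies when every sample of
  # at least one group has >= 1 call at level >= min_sample_variant_level,
  # with that group's mean count and mean level over their thresholds.
  qual <- matrix(FALSE, nP, 4); score <- matrix(-1, nP, 4)
  for (b in seq_along(BASES)) {
    vb <- base_tot[[b]]
    lev <- vb / pmax(vb + ref_cnt, 1L)
    for (grp in list(!is_treated, is_treated)) {
      g_ok <- rowSums(vb[, grp, drop = FALSE] >= 1 &
                      lev[, grp, drop = FALSE] >= th$min_sample_variant_level) == sum(grp) &
        rowMeans(vb[, grp, drop = FALSE]) >= th$min_group_mean_variant_count &
        rowMeans(lev[, grp, drop = FALSE]) >= th$min_group_mean_variant_level
      qual[, b] <- qual[, b] | g_ok
    }
    qual[, b] <- qual[, b] & (ref_idx != b)
    score[, b] <- rowSums(vb)
  }
  score[!qual] <- -1
  var_idx <- max.col(score, ties.method = "first")
  gate2 <- rowSums(qual) > 0
  var_idx[!gate2] <- NA_integer_
  variant_base <- BASES[var_idx]

  pick_var <- function(mats) {
    out <- matrix(0L, nP, nS)
    for (b in seq_along(BASES)) {
      rows <- which(!is.na(var_idx) & var_idx == b)
      out[rows, ] <- mats[[b]][rows, , drop = FALSE]
    }
    out
  }
  var_cnt <- pick_var(base_tot)
  var_fwd <- pick_var(cnt[paste0(BASES, "_fwd")])
  ref_fwd <- pick_ref(cnt[paste0(BASES, "_fwd")])

  # gate 3: other-base contamination
  other <- depth - ref_cnt - var_cnt
  gate3 <- gate2 &
    rowSums(other) / pmax(rowSums(depth), 1L) < th$max_other_base_fraction &
    rowSums(other > th$max_other_base_count_per_sample) == 0

  # variation levels (variant absent in a sample counts as level 0)
  lev <- var_cnt / pmax(var_cnt + ref_cnt, 1L)
  dimnames(lev) <- list(NULL, sample_ids)

  # gate 4: dispersion of the per-sample levels
  lmean <- rowMeans(lev)
  lrange <- apply(lev, 1, max) - apply(lev, 1, min)
  gate4 <- gate3 & lmean > 0 & lrange / pmax(lmean, 1e-300) >= th$min_range_over_mean

  # gate 5: beta-binomial group test with BH correction across the tested
  # positions of this aligner dataset
  test_rows <- which(gate1 & gate4)
  p_raw <- rep(NA_real_, nP)
  for (i in test_rows) {
    ka <- var_cnt[i, !is_treated]; na_ <- ka + ref_cnt[i, !is_treated]
    kb <- var_cnt[i, is_treated];  nb_ <- kb + ref_cnt[i, is_treated]
    oka <- na_ > 0; okb <- nb_ > 0
    if (sum(oka) < 2 || sum(okb) < 2) next
    p_raw[i] <- beta_binomial_test(ka[oka], na_[oka], kb[okb], nb_[okb])$p.value
  }
  p_adj <- rep(NA_real_, nP)
  tested <- !is.na(p_raw)
  p_adj[tested] <- bh_adjust(p_raw[tested])
  gate5 <- gate4 & tested & p_adj < th$alpha_adjusted

  # gate 6: group specificity
  control_mean <- rowMeans(lev[, !is_treated, drop = FALSE])
  treated_mean <- rowMeans(lev[, is_treated, drop = FALSE])
  gate6 <- gate5 & control_mean == 0 & treated_mean >= th$min_treated_mean_level

  t_sel <- is_treated
  positions <- data.frame(
    chrom = upos$chrom, pos = upos$pos, ref = upos$ref,
    variant_base = ifelse(is.na(variant_base), "", variant_base),
    gate1 = gate1, gate2 = gate1 & gate2, gate3 = gate1 & gate3,
    gate4 = gate1 & gate4, gate5 = gate5, gate6 = gate6,
    pass16 = gate1 & gate2 & gate3 & gate4 & gate5 & gate6,
    p_raw = p_raw, p_adj = p_adj,
    control_mean = control_mean, treated_mean = treated_mean,
    t_ref_fwd = rowSums(ref_fwd[, t_sel, drop = FALSE]),
    t_ref_rev = rowSums(ref_cnt[, t_sel, drop = FALSE]) -
      rowSums(ref_fwd[, t_sel, drop = FALSE]),
    t_var_fwd = rowSums(var_fwd[, t_sel, drop = FALSE]),
    t_var_rev = rowSums(var_cnt[, t_sel, drop = FALSE]) -
      rowSums(var_fwd[, t_sel, drop = FALSE]),
    fwd_frac = rowSums(fwd_tot) / pmax(rowSums(depth), 1L),
    stringsAsFactors = FALSE)
  list(positions = positions, levels = lev)
}

#' Strand-bias gate on treated-group pooled counts
#'
#' The Fisher exact test comparing reference and variant calls between the
#' two read directions is applied only when each base-type has at least
#' `strand_min_calls_per_basetype` calls and at least one base-type draws
#' less than `strand_minor_direction_fraction` of its calls from one
#' direction. The gate fails iff the test is applied and its p-value falls
#' below `strand_alpha`.
#'
#' @param treated_counts named numeric vector with elements `ref_fwd`,
#'   `ref_rev`, `var_fwd`, `var_rev`, pooled over treated samples.
#' @param thresholds [filter_thresholds()] record.
#' @return list with `status` (`"pass"`, `"fail"` or `"not_applicable"`)
#'   and `p` (Fisher p-value, `NA` when not applied).
#' @export
strand_bias_gate <- function(treated_counts, thresholds = filter_thresholds()) {
  rc <- treated_counts[c("ref_fwd", "ref_rev")]
  vc <- treated_counts[c("var_fwd", "var_rev")]
  ref_tot <- sum(rc); var_tot <- sum(vc)
  if (ref_tot < thresholds$strand_min_calls_per_basetype ||
      var_tot < thresholds$strand_min_calls_per_basetype)
    return(list(status = "not_applicable", p = NA_real_))
  minor <- c(min(rc) / ref_tot, min(vc) / var_tot)
  if (!any(minor < thresholds$strand_minor_direction_fraction))
    return(list(status = "not_applicable", p = NA_real_))
  p <- fisher_exact_2x2(matrix(c(rc, vc), 2, byrow = TRUE))
  list(status = if (p < thresholds$strand_alpha) "fail" else "pass", p = p)
}

#' Assign the RNA-level edit type from genomic bases and transcribed strand
#'
#' Complements and relabels on the minus strand, writing the change in the
#' RNA alphabet: a genomic C>T on a plus-strand transcript and a genomic
#' G>A on a minus-strand transcript both report as `"C>U"`.
#'
#' @param ref_base,variant_base genomic reference and variant bases.
#' @param strand transcribed strand, `"+"` or `"-"`; vectorized.
#' @return character vector of edit types like `"C>U"`.
#' @export
assign_edit_type <- function(ref_base, variant_base, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  r <- ifelse(strand == "-", complement_base(ref_base), ref_base)
  v <- ifelse(strand == "-", complement_base(variant_base), variant_base)
  paste0(dna_to_rna(r), ">", dna_to_rna(v))
}

#' @noRd
transcript_strand_at <- function(transcripts, chrom, pos) {
  hit <- transcripts$chrom == chrom &
    vapply(seq_len(nrow(transcripts)), function(i)
      pos >= min(transcripts$exon_starts[[i]]) &&
      pos <= max(transcripts$exon_ends[[i]]), logical(1))
  st <- unique(transcripts$strand[hit])
  if (length(st) == 1) st else NA_character_
}

#' @noRd
build_gate_summary <- function(per_aligner, n_concordant, n_strand, n_final) {
  per <- lapply(per_aligner, function(ev) {
    p <- ev$positions
    c(input = nrow(p), depth = sum(p$gate1), candidate = sum(p$gate2),
      other_base = sum(p$gate3), dispersion = sum(p$gate4),
      bb_test_bh = sum(p$gate5), group_specific = sum(p$gate6))
  })
  out <- data.frame(gate = names(per[[1]]), do.call(cbind, per),
                    row.names = NULL, check.names = FALSE)
  rbind2 <- function(df, gate, n) {
    row <- c(list(gate = gate), stats::setNames(as.list(rep(n, ncol(df) - 1)),
                                                names(df)[-1]))
    rbind(df, as.data.frame(row, check.names = FALSE))
  }
  out <- rbind2(out, "concordance", n_concordant)
  out <- rbind2(out, "strand_bias", n_strand)
  out <- rbind2(out, "final_level", n_final)
  out
}

#' Summary statistics over a set of called editing sites
#'
#' @param sites `editing_sites` data frame.
#' @param high_cuts editing-level cutoffs tallied with strict `>` (default
#'   0.20 and 0.30, the conventionally reported high-editing bins).
#' @return object of class `editing_site_summary`: count, mean/SD/min/max of
#'   the editing level, counts above each cutoff, and an edit-type tally.
#' @export
summarize_sites <- function(sites, high_cuts = c(0.20, 0.30)) {
  lv <- sites$edit_level
  n <- length(lv)
  out <- list(
    n_sites = n,
    mean_level = if (n) mean(lv) else NA_real_,
    sd_level = if (n > 1) stats::sd(lv) else NA_real_,
    min_level = if (n) min(lv) else NA_real_,
    max_level = if (n) max(lv) else NA_real_,
    n_above = stats::setNames(vapply(high_cuts, function(ct) sum(lv > ct),
                                     integer(1)),
                              paste0("gt_", high_cuts)),
    edit_types = if (n) table(sites$edit_type) else table(character(0)))
  structure(out, class = "editing_site_summary")
}

#' @export
print.editing_site_summary <- function(x, ...) {
  cat(sprintf("%d editing sites\n", x$n_sites))
  if (x$n_sites) {
    cat(sprintf("  editing level: mean %.3f, sd %.3f, range %.3f-%.3f\n",
                x$mean_level, x$sd_level, x$min_level, x$max_level))
    for (nm in names(x$n_above))
      cat(sprintf("  level > %s: %d sites\n", sub("gt_", "", nm), x$n_above[[nm]]))
    cat("  edit types: ",
        paste(sprintf("%s: %d", names(x$edit_types), x$edit_types),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.editing_sites <- function(x, ...) {
  cat(sprintf("editing_sites: %d called site(s)\n", nrow(x)))
  gs <- attr(x, "gate_summary")
  if (!is.null(gs)) {
    cat("step-wise filter survivors:\n")
    print.data.frame(gs, row.names = FALSE)
  }
  if (nrow(x)) {
    cat("\n")
    print.data.frame(utils::head(
      as.data.frame(x)[, c("chrom", "pos", "strand", "edit_type",
                           "edit_level", "p_adjusted")], 10),
      row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.editing_sites <- function(object, ...) summarize_sites(object, ...)

#' @export
plot.editing_sites <- function(x, breaks = seq(0, 1, by = 0.02), ...) {
  graphics::hist(x$edit_level, breaks = breaks, xlab = "editing level",
                 main = "Called editing sites", col = "grey70", ...)
  invisible(x)
}
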