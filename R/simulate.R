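# Synthetic base-call data with known ground truth: directional RNA-Seq
# style counts for two sample groups, correlated between two aligner
# datasets by read thinning, with planted editing levels, sequence
# contexts and stem-loops.

#' Configuration for the base-call simulator
#'
#' Defaults define the package's reference benchmark: 2,000 genomic
#' positions, 10% edited with per-site levels drawn from a Beta(1.3, 8)
#' rescaled to `[0.05, 0.6]` (right-skewed, mimicking observed editing-level
#' distributions), per-sample depths NB(mean 80, size 8), per-base miscall
#' probability 0.002 into the transition channel, balanced read directions,
#' 1% of null positions carrying a direction-skewed artifact, and two
#' aligner datasets each retaining 95% of the same latent reads.
#'
#' @param n_positions number of genomic positions simulated.
#' @param fraction_edited fraction of positions truly edited in the treated
#'   group.
#' @param level_shape Beta shape parameters for true editing levels.
#' @param level_range range the Beta draw is rescaled to.
#' @param depth_mean,depth_size negative-binomial depth model per sample.
#' @param error_rate per-base miscall probability into the designated
#'   variant (transition) channel; each remaining base receives
#'   `error_rate/3`.
#' @param strand_fraction expected fraction of calls on the forward read
#'   direction.
#' @param strand_bias_artifact_fraction fraction of null positions given
#'   treated-only variant calls drawn entirely from one read direction
#'   (alignment-artifact mimic).
#' @param artifact_level variant level of those artifact positions.
#' @param aligner_retention binomial thinning probability linking each
#'   aligner dataset to the latent reads.
#' @param n_control,n_treated samples per group.
#' @param sample_rho between-replicate intraclass correlation of treated
#'   editing levels.
#' @param stemloop_fraction fraction of edited sites with a planted
#'   flanking inverted repeat (loop 3-4 nt ending at the edited C).
#' @param plant_context plant the preferred 5'-context (C/U-rich -1, CCC/
#'   ACC/UCC-style -2) around edited Cs.
#' @param seed RNG seed; all randomness flows from it.
#' @return object of class `simulation_config` (named list).
#' @export
simulation_config <- function(n_positions = 2000,
                              fraction_edited = 0.10,
                              level_shape = c(1.3, 8),
                              level_range = c(0.05, 0.6),
                              depth_mean = 80,
                              depth_size = 8,
                              error_rate = 0.002,
                              strand_fraction = 0.5,
                              strand_bias_artifact_fraction = 0.01,
                              artifact_level = 0.08,
                              aligner_retention = 0.95,
                              n_control = 3,
                              n_treated = 3,
                              sample_rho = 0.005,
                              stemloop_fraction = 0.98,
                              plant_context = TRUE,
                              seed = 1) {
  cfg <- as.list(environment())
  probs <- c("fraction_edited", "error_rate", "strand_fraction",
             "strand_bias_artifact_fraction", "artifact_level",
             "aligner_retention", "sample_rho", "stemloop_fraction")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must be in [0, 1]", p)
  if (cfg$depth_mean <= 0 || cfg$depth_size <= 0)
    stopf("depth model parameters must be positive")
  if (cfg$n_positions < 1) stopf("n_positions must be >= 1")
  structure(cfg, class = "simulation_config")
}

# transition partner of each base (the designated error/variant channel)
TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

#' Simulate a two-group, two-aligner base-call dataset with ground truth
#'
#' Edited positions carry treated-sample variant counts
#' `Binomial(depth, p_s)` where the per-sample `p_s` jitters around the
#' site's true level with intraclass correlation `sample_rho`; control
#' samples (and all samples at null positions) draw variant-channel counts
#' `Binomial(depth, error_rate)`. Both aligner datasets are binomial
#' thinnings of the same latent counts. The reference sequence embeds the
#' preferred sequence context and a flanking stem-loop around edited Cs.
#' Fully reproducible from `cfg$seed` (the caller's RNG state is
#' preserved).
#'
#' @param cfg [simulation_config()].
#' @return list with `profiles` (named list of two long profile data
#'   frames, aligners `"alnA"` and `"alnB"`), `samples` (sample sheet),
#'   `truth` (position table with `is_edited`, `true_level`, `strand`,
#'   `artifact`, `mean_depth`), `genome` (named character vector),
#'   `transcripts` (one plus-strand coding transcript spanning the
#'   simulated contig), and `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_positions
  nC <- cfg$n_control; nT <- cfg$n_treated; nS <- nC + nT
  sample_ids <- c(paste0("ctrl", seq_len(nC)), paste0("a3g", seq_len(nT)))
  is_treated <- c(rep(FALSE, nC), rep(TRUE, nT))
  spacing <- 30L
  centers <- spacing * seq_len(n)
  glen <- spacing * (n + 1L)
  gseq <- sample(BASES, glen, replace = TRUE)

  n_edit <- round(cfg$fraction_edited * n)
  edited <- rep(FALSE, n)
  if (n_edit > 0) edited[sample.int(n, n_edit)] <- TRUE
  null_idx <- which(!edited)
  n_art <- round(cfg$strand_bias_artifact_fraction * length(null_idx))
  artifact <- rep(FALSE, n)
  if (n_art > 0) artifact[sample(null_idx, n_art)] <- TRUE

  true_level <- rep(NA_real_, n)
  if (n_edit > 0)
    true_level[edited] <- cfg$level_range[1] +
      diff(cfg$level_range) * stats::rbeta(n_edit, cfg$level_shape[1],
                                           cfg$level_shape[2])

  # plant reference context and stem-loops around edited Cs
  for (i in which(edited)) {
    ce <- centers[i]
    gseq[ce] <- "C"
    planted_loop <- 0L
    if (stats::runif(1) < cfg$stemloop_fraction) {
      lp <- sample(c(3L, 4L), 1, prob = c(0.3, 0.7))
      k <- sample(3:10, 1, prob = c(0.25, 0.33, 0.18, 0.10, 0.06, 0.04,
                                    0.02, 0.02))
      arm <- c(sample(BASES, k - 1L, replace = TRUE),
               sample(c("C", "T"), 1))   # last arm base pairs to an A/G at +1
      gseq[(ce - lp - k + 1L):(ce - lp)] <- arm
      gseq[(ce + 1L):(ce + k)] <- strsplit(revcomp(paste(arm, collapse = "")),
                                           "")[[1]]
      planted_loop <- lp
    } else if (cfg$plant_context) {
      gseq[ce - 3L] <- sample(c("C", "G", "T"), 1)
      gseq[ce + 1L] <- sample(c("A", "G"), 1)
    }
    if (cfg$plant_context) {
      # 5'-neighbor preferences of the edited C
      gseq[ce - 1L] <- sample(BASES[c(2, 4, 1, 3)], 1,
                              prob = c(0.861, 0.118, 0.013, 0.008))
      gseq[ce - 2L] <- sample(c("C", "A", "T", "G"), 1,
                              prob = c(0.31, 0.29, 0.27, 0.13))
      if (planted_loop == 4L) gseq[ce - 3L] <- sample(c("C", "G", "T"), 1)
    }
  }

  ref <- gseq[centers]
  varb <- unname(TRANSITION[ref])
  other <- t(vapply(seq_len(n), function(i) setdiff(BASES, c(ref[i], varb[i])),
                    character(2)))

  # latent counts -------------------------------------------------------
  depth <- matrix(pmax(stats::rnbinom(n * nS, mu = cfg$depth_mean,
                                      size = cfg$depth_size), 1L), n, nS)
  p_mat <- matrix(cfg$error_rate, n, nS)
  if (n_edit > 0) {
    rho <- cfg$sample_rho
    for (s in which(is_treated)) {
      L <- true_level[edited]
      p_mat[edited, s] <- if (rho > 0)
        stats::rbeta(n_edit, L * (1 - rho) / rho, (1 - L) * (1 - rho) / rho)
      else L
    }
  }
  if (n_art > 0) p_mat[artifact, is_treated] <- cfg$artifact_level
  v <- matrix(stats::rbinom(n * nS, depth, p_mat), n, nS)
  e1 <- matrix(stats::rbinom(n * nS, depth, cfg$error_rate / 3), n, nS)
  e2 <- matrix(stats::rbinom(n * nS, depth, cfg$error_rate / 3), n, nS)
  rf <- pmax(depth - v - e1 - e2, 0L)

  sf <- cfg$strand_fraction
  split_fwd <- function(m) matrix(stats::rbinom(length(m), m, sf), nrow(m))
  v_fwd <- split_fwd(v); rf_fwd <- split_fwd(rf)
  e1_fwd <- split_fwd(e1); e2_fwd <- split_fwd(e2)
  if (n_art > 0) v_fwd[artifact, is_treated] <- v[artifact, is_treated]

  latent <- list(ref_f = rf_fwd, ref_r = rf - rf_fwd,
                 var_f = v_fwd, var_r = v - v_fwd,
                 o1_f = e1_fwd, o1_r = e1 - e1_fwd,
                 o2_f = e2_fwd, o2_r = e2 - e2_fwd)

  chrom <- "sim1"
  mk_profile <- function(retention) {
    thin <- lapply(latent, function(m)
      matrix(stats::rbinom(length(m), m, retention), nrow(m)))
    out <- vector("list", nS)
    for (s in seq_len(nS)) {
      cnt <- matrix(0L, n, 8L, dimnames = list(NULL, COUNT_COLS))
      put <- function(base, strand, val) {
        cnt[cbind(seq_len(n), match(paste(base, strand, sep = "_"),
                                    COUNT_COLS))] <<- val
      }
      put(ref, "fwd", thin$ref_f[, s]); put(ref, "rev", thin$ref_r[, s])
      put(varb, "fwd", thin$var_f[, s]); put(varb, "rev", thin$var_r[, s])
      put(other[, 1], "fwd", thin$o1_f[, s]); put(other[, 1], "rev", thin$o1_r[, s])
      put(other[, 2], "fwd", thin$o2_f[, s]); put(other[, 2], "rev", thin$o2_r[, s])
      out[[s]] <- data.frame(chrom = chrom, pos = centers, ref = ref,
                             sample_id = sample_ids[s], cnt,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  profiles <- list(alnA = mk_profile(cfg$aligner_retention),
                   alnB = mk_profile(cfg$aligner_retention))

  genome <- stats::setNames(paste(gseq, collapse = ""), chrom)
  cds_len <- 3L * (glen %/% 3L)
  transcripts <- data.frame(transcript_id = "SIMTX1", chrom = chrom,
                            strand = "+", stringsAsFactors = FALSE)
  transcripts$exon_starts <- list(1L)
  transcripts$exon_ends <- list(glen)
  transcripts$cds_start <- 1L
  transcripts$cds_end <- cds_len

  list(profiles = profiles,
       samples = data.frame(sample_id = sample_ids,
                            group = ifelse(is_treated, "treated", "control"),
                            stringsAsFactors = FALSE),
       truth = data.frame(chrom = chrom, pos = centers,
                          is_edited = edited, true_level = true_level,
                          strand = "+", artifact = artifact,
                          mean_depth = rowMeans(depth),
                          stringsAsFactors = FALSE),
       genome = genome,
       transcripts = transcripts,
       config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits per-aligner, per-sample pileup files (`<aligner>_<sample>.pu`),
#' the reference FASTA, the sample sheet, the truth table and the
#' transcript table. Output is byte-identical for identical configurations.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the output directory.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (al in names(sim$profiles)) {
    prof <- sim$profiles[[al]]
    for (sid in sim$samples$sample_id) {
      sub <- prof[prof$sample_id == sid, , drop = FALSE]
      write_pileup(sub, file.path(outdir, paste0(al, "_", sid, ".pu")))
    }
  }
  write_fasta(sim$genome, file.path(outdir, "genome.fa"))
  utils::write.table(sim$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$true_level <- ifelse(is.na(truth$true_level), "NA",
                             sprintf("%.17g", truth$true_level))
  utils::write.table(truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_transcript_table(sim$transcripts, file.path(outdir, "transcripts.tsv"))
  invisible(outdir)
}

#' Score called sites against simulation ground truth
#'
#' @param called `editing_sites` data frame (or any data frame with
#'   `chrom`, `pos`, `edit_level`).
#' @param truth truth table from [simulate_dataset()].
#' @param level_min,depth_min restrict the sensitivity denominator to truly
#'   edited positions with `true_level >= level_min` and
#'   `mean_depth >= depth_min` (defaults 0: all edited positions).
#' @return list with `sensitivity`, `fdr` (fraction of calls not truly
#'   edited; 0 when nothing is called), `level_mae` (mean absolute error of
#'   `edit_level` over true-positive calls), and the underlying counts.
#' @export
score_calls <- function(called, truth, level_min = 0, depth_min = 0) {
  key <- function(ch, po) paste(ch, po)
  called_k <- key(called$chrom, called$pos)
  edited_k <- key(truth$chrom, truth$pos)[truth$is_edited]
  denom_sel <- truth$is_edited & truth$true_level >= level_min &
    truth$mean_depth >= depth_min
  denom_k <- key(truth$chrom, truth$pos)[denom_sel]
  tp_denom <- sum(denom_k %in% called_k)
  fp <- sum(!called_k %in% edited_k)
  tp_all <- called_k %in% edited_k
  mae <- if (any(tp_all)) {
    idx <- match(called_k[tp_all], key(truth$chrom, truth$pos))
    mean(abs(called$edit_level[tp_all] - truth$true_level[idx]))
  } else NA_real_
  list(sensitivity = if (length(denom_k)) tp_denom / length(denom_k) else NA_real_,
       fdr = if (length(called_k)) fp / length(called_k) else 0,
       level_mae = mae,
       n_called = length(called_k), n_true = sum(truth$is_edited),
       n_true_eligible = length(denom_k), n_false_calls = fp)
}
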