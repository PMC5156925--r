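# Independent brute-force oracles and fixture generators used across the
# suite. These deliberately avoid the package's own code paths.

# -- two-sided Fisher p by exhaustive hypergeometric enumeration ----------
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(1)
  klo <- max(0, c1 - (n - r1)); khi <- min(r1, c1)
  ks <- klo:khi
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  pobs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# -- brute-force Benjamini-Hochberg step-up ------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# -- brute-force flanking inverted-repeat search --------------------------
# Exhaustive over (i, j, k) with per-base complement comparison; returns
# only the maximal arm length (tie-breaking is not part of the contract
# checked against this oracle).
oracle_max_arm <- function(window, min_arm = 3, max_arm = 10) {
  comp <- c(A = "U", C = "G", G = "C", U = "A", T = "A")
  ch <- strsplit(chartr("Tt", "Uu", toupper(window)), "")[[1]]
  L <- length(ch)
  center <- (L + 1L) %/% 2L
  best <- 0L
  for (k in min_arm:max_arm) {
    if (k > center - 1L || center + k > L + 1L) next
    for (i in seq_len(max(center - k, 0L))) {
      for (j in (center + 1L):(L - k + 1L)) {
        ok <- TRUE
        for (t in 0:(k - 1L)) {
          if (comp[[ch[i + t]]] != ch[j + k - 1L - t]) { ok <- FALSE; break }
        }
        if (ok && k > best) best <- k
      }
    }
  }
  best
}

# -- binomial likelihood-ratio test on pooled counts ----------------------
oracle_binomial_lrt_p <- function(ka, na, kb, nb) {
  ll <- function(k, n, p) sum(stats::dbinom(k, n, p, log = TRUE))
  p0 <- (sum(ka) + sum(kb)) / (sum(na) + sum(nb))
  pa <- sum(ka) / sum(na); pb <- sum(kb) / sum(nb)
  clamp <- function(p) min(max(p, 1e-12), 1 - 1e-12)
  stat <- 2 * (ll(ka, na, clamp(pa)) + ll(kb, nb, clamp(pb)) -
               ll(c(ka, kb), c(na, nb), clamp(p0)))
  stats::pchisq(max(0, stat), df = 1, lower.tail = FALSE)
}

# -- random fixtures ------------------------------------------------------

# Build a pileup line from explicit counts, optionally decorating it with
# read starts/ends and indels, so the generator's counts are the truth.
random_pileup_line <- function(chrom, pos, ref, counts, decorate = TRUE) {
  syms <- character(0)
  for (b in c("A", "C", "G", "T")) for (st in c("fwd", "rev")) {
    k <- counts[[paste(b, st, sep = "_")]]
    if (k == 0) next
    sym <- if (b == ref) { if (st == "fwd") "." else "," }
           else { if (st == "fwd") b else tolower(b) }
    syms <- c(syms, rep(sym, k))
  }
  if (length(syms)) syms <- sample(syms)
  if (decorate && length(syms)) {
    i <- sample(length(syms), 1)
    syms[i] <- paste0("^~", syms[i])                    # read start
    j <- sample(length(syms), 1)
    syms[j] <- paste0(syms[j], "$")                     # read end
    k <- sample(length(syms), 1)
    ins <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
    syms[k] <- paste0(syms[k], "+3", ins)               # insertion
  }
  depth <- sum(unlist(counts))
  paste(chrom, pos, ref, depth,
        if (depth) paste(syms, collapse = "") else "*",
        if (depth) strrep("I", depth) else "*")
}

random_counts <- function(max_per_cell = 5) {
  cnt <- as.list(stats::setNames(
    sample(0:max_per_cell, 8, replace = TRUE),
    c(t(outer(c("A", "C", "G", "T"), c("fwd", "rev"), paste, sep = "_")))))
  cnt
}

random_window <- function(width = 25) {
  half <- (width - 1) %/% 2
  paste(c(sample(c("A", "C", "G", "U"), half, TRUE), "C",
          sample(c("A", "C", "G", "U"), half, TRUE)), collapse = "")
}

# -- toy genome / transcript for effect classification --------------------
# Plus-strand gene: 5'UTR (1-10), CDS over two exons, 3'UTR, intron between.
toy_gene <- function() {
  # CDS: ATG CAA CGG CCC TAA  (M Q R P *), split 9 + 6 across two exons
  exon1 <- paste0("GGGGGGGGGG", "ATGCAACGG")      # 1-10 UTR, 11-19 CDS
  intron <- "TTTTTTTTTT"                          # 20-29
  exon2 <- paste0("CCCTAA", "AAAAA")              # 30-35 CDS, 36-40 UTR
  genome <- c(chrT = paste0(exon1, intron, exon2))
  tx <- data.frame(transcript_id = "TOY1", chrom = "chrT", strand = "+",
                   stringsAsFactors = FALSE)
  tx$exon_starts <- list(c(1L, 30L))
  tx$exon_ends <- list(c(19L, 40L))
  tx$cds_start <- 11L
  tx$cds_end <- 35L
  list(genome = genome, tx = tx)
}

# Small simulated dataset for caller-level tests.
small_sim <- function(seed = 11, n = 400, ...) {
  simulate_dataset(simulation_config(n_positions = n, seed = seed, ...))
}
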