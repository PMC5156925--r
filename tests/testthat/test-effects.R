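test_that("CDS edits translate to the expected codon consequences", {
  g <- toy_gene()
  # CAA codon (cDNA 4-6), C at its first position: C>T makes TAA = stop
  eff <- classify_site(list(chrom = "chrT", pos = 14, ref_base = "C",
                            variant_base = "T"), g$tx, g$genome)
  expect_equal(eff$feature, "CDS")
  expect_equal(eff$consequence, "nonsense")
  expect_equal(eff$cdna_change, "c.C4T")
  expect_equal(eff$protein_change, "p.Q2X")
  # CGG codon, first position: C>T makes TGG = Trp (missense R>W)
  eff2 <- classify_site(list(chrom = "chrT", pos = 17, ref_base = "C",
                             variant_base = "T"), g$tx, g$genome)
  expect_equal(eff2$consequence, "missense")
  expect_equal(eff2$protein_change, "p.R3W")
  # CCC codon, third position: C>T makes CCT = Pro (synonymous)
  eff3 <- classify_site(list(chrom = "chrT", pos = 32, ref_base = "C",
                             variant_base = "T"), g$tx, g$genome)
  expect_equal(eff3$consequence, "synonymous")
  expect_equal(eff3$cdna_change, "c.C12T")
  # TAA stop, second position: A>G would lose the stop (T>C path checked
  # via the complementary construction below); here edit A at pos 34
  eff4 <- classify_site(list(chrom = "chrT", pos = 34, ref_base = "A",
                             variant_base = "C"), g$tx, g$genome)
  expect_equal(eff4$consequence, "stop-loss")
})

test_that("non-CDS features are assigned by interval arithmetic", {
  g <- toy_gene()
  feat <- function(pos) classify_site(list(chrom = "chrT", pos = pos,
                                           ref_base = "G", variant_base = "A"),
                                      g$tx, g$genome)$feature
  expect_equal(feat(5), "5'UTR")
  expect_equal(feat(38), "3'UTR")
  expect_equal(feat(25), "intronic")
  expect_equal(classify_site(list(chrom = "chrT", pos = 300, ref_base = "G",
                                  variant_base = "A"), g$tx, g$genome,
                             flank = 1000)$feature, "untranscribed")
  expect_equal(classify_site(list(chrom = "chrT", pos = 3000, ref_base = "G",
                                  variant_base = "A"), g$tx, g$genome)$feature,
               "intergenic")
  expect_equal(classify_site(list(chrom = "chrZ", pos = 5, ref_base = "G",
                                  variant_base = "A"), g$tx, g$genome)$feature,
               "intergenic")
  # non-coding transcript -> ncRNA
  nc <- g$tx; nc$cds_start <- NA; nc$cds_end <- NA
  expect_equal(classify_site(list(chrom = "chrT", pos = 14, ref_base = "C",
                                  variant_base = "T"), nc, g$genome)$feature,
               "ncRNA")
})

test_that("minus-strand classification mirrors the plus-strand construction", {
  g <- toy_gene()
  L <- nchar(g$genome[[1]])
  rc_genome <- c(chrT = revcomp(g$genome[[1]]))
  mirror <- function(p) L - p + 1L
  tx_m <- g$tx
  tx_m$strand <- "-"
  tx_m$exon_starts <- list(sort(mirror(c(g$tx$exon_ends[[1]]))))
  tx_m$exon_ends <- list(sort(mirror(c(g$tx$exon_starts[[1]]))))
  tx_m$cds_start <- mirror(g$tx$cds_end)
  tx_m$cds_end <- mirror(g$tx$cds_start)
  for (pos in c(14, 17, 32)) {
    plus <- classify_site(list(chrom = "chrT", pos = pos, ref_base = "C",
                               variant_base = "T"), g$tx, g$genome)
    minus <- classify_site(list(chrom = "chrT", pos = mirror(pos),
                                ref_base = "G", variant_base = "A"),
                           tx_m, rc_genome)
    expect_equal(minus$consequence, plus$consequence)
    expect_equal(minus$cdna_change, plus$cdna_change)
    expect_equal(minus$protein_change, plus$protein_change)
  }
})

test_that("the whole toy CDS differs in exactly one residue after an edit", {
  g <- toy_gene()
  translate_cds <- function(genome) {
    cds <- paste0(substr(genome[[1]], 11, 19), substr(genome[[1]], 30, 35))
    as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  }
  before <- translate_cds(g$genome)
  edited <- g$genome
  substr(edited[[1]], 17, 17) <- "T"
  after <- translate_cds(edited)
  diffs <- which(strsplit(before, "")[[1]] != strsplit(after, "")[[1]])
  expect_length(diffs, 1)
  eff <- classify_site(list(chrom = "chrT", pos = 17, ref_base = "C",
                            variant_base = "T"), g$tx, g$genome)
  expect_equal(sprintf("p.%s%d%s", strsplit(before, "")[[1]][diffs], diffs,
                       strsplit(after, "")[[1]][diffs]),
               eff$protein_change)
})

test_that("a CDS whose length is not a codon multiple rejects the model", {
  g <- toy_gene()
  bad <- g$tx; bad$cds_end <- 34L
  expect_warning(eff <- classify_site(list(chrom = "chrT", pos = 14,
                                           ref_base = "C", variant_base = "T"),
                                      bad, g$genome), "divisible")
  expect_equal(eff$feature, "unknown")
})

test_that("feature tallies sum to the classified sites", {
  g <- toy_gene()
  sites <- data.frame(chrom = "chrT", pos = c(14, 26, 32, 5),
                      ref_base = c("C", "T", "C", "G"),
                      variant_base = c("T", "C", "T", "A"),
                      stringsAsFactors = FALSE)
  eff <- classify_sites(sites, g$tx, g$genome)
  tall <- feature_tally(eff)
  expect_equal(sum(tall$n), 4)
  expect_equal(tall$n[tall$consequence == "nonsense"], 1L)
  expect_equal(tall$n[tall$consequence == "synonymous"], 1L)
  expect_equal(nrow(feature_tally(eff[0, ])), 0)
})
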