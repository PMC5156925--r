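Package: edcall
Title: Detection and Characterization of Site-Specific C-to-U RNA Editing
    from RNA-Seq Base Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A step-wise pipeline for discovering site-specific C-to-U RNA
    editing from two-group, dual-aligner RNA-Seq experiments. Parses
    samtools-style pileup text into strand-resolved base-call profiles,
    applies a configurable cascade of depth, candidate-variant,
    contamination, dispersion, group-specificity, aligner-concordance and
    strand-bias filters around a two-tailed beta-binomial group test with
    Benjamini-Hochberg correction, and annotates called sites with their
    sequence context (5'-neighbor preferences, trinucleotide contexts,
    position frequency matrices, degenerate motif matching), flanking
    inverted-repeat stem-loop structure, and predicted codon-level
    consequence given transcript models. Includes quantification of editing
    levels from Sanger chromatogram peak heights with a detection threshold,
    and a synthetic base-call simulator with ground truth for recovery
    benchmarking of the caller.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
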