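---
title: "Discovering site-specific C-to-U RNA editing from base-call data"
author: "edcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering site-specific C-to-U RNA editing from base-call data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcall)
```

## The problem

Cytidine deaminases of the APOBEC family can convert cytidine to uridine in
cellular mRNAs. Against a reference genome, such an edit appears as a C>T
mismatch in RNA-Seq reads from a plus-strand transcript, or a G>A mismatch
from a minus-strand transcript, at a fraction of reads (the *editing
level*) that is typically 5--50%. Distinguishing genuine, enzyme-dependent
editing from sequencing error, alignment artifacts and germline variation
is the central difficulty: a naive mismatch scan over ~30 million
transcribed positions produces overwhelmingly false signals.

`edcall` implements a conservative discovery design built around three
ideas:

1. **Group specificity.** Editing is compared between deaminase-expressing
   (treated) and control transfectants, three biological replicates each.
   A site must show signal in *every* treated replicate and *no* signal in
   any control replicate.
2. **Statistical testing with overdispersion.** Replicate editing levels
   vary beyond binomial sampling; the group comparison uses a two-tailed
   beta-binomial likelihood-ratio test with Benjamini--Hochberg correction.
3. **Artifact gates.** Candidate sites must survive a strand-bias Fisher
   test (alignment artifacts produce variant calls concentrated in one
   read direction) and must be called independently in two different
   aligners' outputs.

Downstream, the package characterizes called sites: flanking sequence
context (the deaminase prefers a pyrimidine at the 5' neighbor, summarized
by the degenerate motif `[CGU]N[CU]C[AG]` around the edited C), flanking
inverted repeats capable of forming stem-loops with the edited C at the 3'
end of the loop, predicted codon-level consequences, and editing
quantification from Sanger chromatogram peak heights.

## The filter cascade

`call_editing_sites()` evaluates, per aligner dataset and in order:

1. **Depth**: every sample has >= 6 A/C/G/T calls and each group's mean
   depth is >= 9. (The group rule is read as a *mean*: a group-sum reading
   would be implied by the per-sample rule and never binds.)
2. **Candidate variant**: some non-reference base has >= 1 call at a
   variation level >= 0.02 in *all* samples of at least one group, with
   that group's mean count >= 1.3 and mean level >= 0.03. The variation
   level is `variant / (variant + reference)` calls.
3. **Contamination**: calls for bases other than reference and variant
   must stay below 1% of all calls and <= 1 call in every sample.
4. **Dispersion**: the six per-sample levels must satisfy
   `(max - min)/mean >= 2`. For group-specific editing (controls at 0)
   this always holds; it removes flat, SNP-like variation.
5. **Beta-binomial test**: BH-adjusted two-sided p < 0.05, adjusted within
   the aligner dataset across all tested positions.
6. **Group specificity**: the control-group mean level must be exactly 0
   and the treated-group mean >= 0.04. This is the asymmetric reading of
   the rule: any control signal at all vetoes the site, while treated
   signal must clear a floor -- the combination that yields call sets
   with level 0 in every control sample and > 5% in every treated one.
7. **Concordance**: gates 1--6 must pass independently in both aligner
   datasets (same position, same variant base).
8. **Strand bias**: on treated-group pooled counts, a Fisher exact test of
   reference/variant calls by read direction. Applied only when each
   base-type has >= 8 calls and at least one base-type draws < 25% of its
   calls from one direction; failure is p < 0.05. The counts are
   aligner-specific, so the gate runs per aligner and a failure in either
   vetoes the site.
9. **Final level**: the editing level -- the mean over aligners of the
   treated-group mean level -- must exceed 0.05.

Every threshold lives in `filter_thresholds()` and is compared with the
exact strictness documented there (e.g. `> 0.05`, `>= 0.02`); levels are
carried at full precision. The per-gate survivor table is attached to the result
(`attr(sites, "gate_summary")`) and emitted by the CLI as `gates.tsv`,
mirroring the step-wise filtering account such analyses conventionally
report.

The transcribed strand is taken from read directionality when >= 90% of a
site's calls share a direction, falling back to supplied transcript
models, else the site is reported with unknown strand and its raw genomic
variant type. With a paired-end directional protocol collapsed into plain
pileup counts, read direction alone is usually uninformative (mates map to
both strands), which is why the transcript-model fallback matters.

## The beta-binomial test

For observations $(k_i, n_i)$ (variant and informative calls), the
beta-binomial model with mean $\mu$ and intraclass correlation $\rho$ uses
shape parameters $\alpha = \mu(1-\rho)/\rho$, $\beta =
(1-\mu)(1-\rho)/\rho$; $\rho \to 0$ recovers the binomial. The test is a
likelihood-ratio test of a common $\mu$ (H0) against group-specific
$\mu_a, \mu_b$ (H1), referred to $\chi^2_1$.

Two numerical decisions matter:

* **The overdispersion is shared across hypotheses.** $\rho$ is estimated
  by profile maximum likelihood *jointly with the null fit* and held fixed
  for the H1 fit. Re-estimating $\rho$ under each hypothesis is markedly
  anticonservative with three replicates per group (null rejection ~0.095
  at $\alpha = 0.05$, depth ~100), because the H1 fit underestimates
  $\rho$ from six observations; sharing the null estimate restores
  near-nominal behavior (~0.045--0.05, measured over 20,000 null
  simulations). The cost is conservatism when the groups differ strongly
  (the null $\hat\rho$ absorbs part of the group difference), so reported
  p-values for clear sites are larger than their exact bootstrap
  counterparts -- a benign direction for discovery control.
* **Small samples fall back to a parametric bootstrap.** When either
  group's total depth is below 50, the $\chi^2_1$ reference is replaced by
  resampling under the fitted null. $\rho$ is clamped to
  $[10^{-9}, 0.999]$; a boundary fit at the binomial limit is checked
  explicitly. All-zero inputs return p = 1 by convention.

`fisher_exact_2x2()` uses the minimum-likelihood two-sided convention
(summing hypergeometric probabilities no larger than the observed
table's), and `bh_adjust()` the standard step-up procedure; both are
backed by `stats` and cross-checked in the test suite against exhaustive
enumeration and a brute-force step-up implementation.

## Sequence context, stem-loops and consequences

Flank windows are 25 nt, transcript-oriented, RNA-alphabet, with the
edited C at position 13 (offset 0). `neighbor_distribution()`,
`trinucleotide_contexts()` and `build_pfm()` summarize base preferences;
information content is $2 - H$ bits per column. `match_motif()` evaluates
the degenerate context `[CGU]N[CU]C[AG]` over offsets $-3..+1$, with `N`
matching any base; DNA input is normalized so `TCC` and `UCC` are one
context.

`find_inverted_repeat()` searches exhaustively for the longest pair of
strict reverse-complement arms (3--10 nt by default) with the left arm
entirely 5' and the right arm entirely 3' of the center; G·U wobble pairs
are *not* counted, because an inverted repeat in the sequence sense is a
strict reverse complement. Ties are broken toward the smallest loop, then
the most center-proximal left arm, then the leftmost right arm -- an
arbitrary but fixed rule that never affects the reported arm length.
`call_loop_model()` additionally pins the right arm to start immediately
3' of the edited C, caps the loop (which ends at the C) at 7 nt, accepts
arms down to 2 nt (the smallest flanking palindrome observed among
validated sites), and tolerates one unpaired nucleotide inside an arm,
flagged `interrupted`; uninterrupted pairings win ties.
`background_repeat_fraction()` samples C-centered windows uniformly (with
replacement) from a transcriptome to put the foreground fractions in
context.

`classify_site()` assigns gene features by interval arithmetic over a
plain exon/CDS table (1-based inclusive coordinates) and translates the
affected codon with the standard genetic code; `untranscribed` means
within 1 kb of a transcript boundary. When several transcripts overlap, a
fixed priority (CDS > UTR > ncRNA > intron, then lexicographic id) picks
the reported model, with all overlaps listed -- deterministic, in the
spirit of annotation tools, without reimplementing one. Models whose
spliced CDS length is not a codon multiple are rejected with a warning.

`sanger_level()` converts major/minor chromatogram peak heights to
`minor/(major + minor)`. Because peak-calling software only reports a
minor peak at >= 5% of the major peak's height, the smallest measurable
level is $0.05/1.05 \approx 0.048$; below it the value is censored
(reported as 0 with a flag, so replicate means can include or exclude
censored calls).

## The simulator and what passing tests mean

`simulate_dataset()` generates the statistical structure the caller
assumes, with ground truth:

* Depths are NB(mean 80, size 8) per sample -- a realistic RNA-Seq
  coverage spread at the benchmark scale of 2,000 positions.
* 10% of positions are edited; true levels are Beta(1.3, 8) rescaled to
  [0.05, 0.6], a right-skewed distribution whose mean (~13%) and tail
  mimic published editing-level distributions (means near 11%, maxima
  near 50%).
* Treated replicate levels jitter around the site level with intraclass
  correlation 0.005 -- replicate transfections of the same construct
  track each other closely; this value keeps the between-replicate spread
  of a 10%-edited site at roughly one percentage point.
* Sequencing miscalls enter the designated variant (transition) channel
  at 0.002 per call, and each remaining base at 0.002/3; controls carry
  *only* miscalls ("zero control background" in the editing sense).
* 1% of null positions receive treated-only variant calls drawn entirely
  from one read direction at level 0.08 -- the alignment-artifact mimic
  the strand-bias gate exists for.
* Both aligner datasets are binomial thinnings (retention 0.95) of the
  same latent counts, so concordance behaves like the same reads mapped
  twice rather than independent experiments.
* Reference windows around edited Cs embed the preferred 5' context and,
  for 98% of sites, a flanking stem-loop (loop 3--4 nt ending at the C,
  arm lengths peaking at 4 nt).

All randomness flows from one seed; identical configurations reproduce
byte-identical outputs, including written pileups.

What the simulation does *not* emulate: germline SNPs and homozygous
variants of the cell line (subtracting them is out of scope here), mapping
biases that differ systematically between aligners, position-correlated
error profiles, and real transcriptome sequence composition. Recovery
numbers on this benchmark therefore speak to the cascade's statistical
behavior under its own assumptions, not to performance on real libraries.

One property of the design deserves emphasis: the strict zero-control
gate bounds attainable sensitivity. A site is lost whenever *any* control
replicate shows even one variant-channel miscall in either aligner
dataset, so with per-call miscall rate $e$ and depth $d$ the expected
ceiling is roughly $E[(1-e)^d]^3$ -- about 0.62 at $e = 0.002$, $d \sim
80$, independent of how strongly the site is edited. The benchmark's
measured sensitivity (~0.55 for sites with true level >= 0.10 and depth
>= 50) sits just under this ceiling, while the empirical FDR is ~0 and
the mean absolute error of recovered levels is ~0.02. That trade -- high
purity at a steep sensitivity cost that grows with sequencing error --
is intrinsic to the zero-control rule, and is the main quantitative
caveat for reusing these thresholds at higher error rates or depths.

## Benchmark sizes and runtime

The shipped tests and the acceptance script use problem sizes chosen to
exercise every code path at interactive runtimes: 2,000-position
simulations with three seeds for recovery scoring, 2,000 null datasets
for type-I calibration, 1,000 random windows against the brute-force
inverted-repeat enumerator, 500 random tables against the Fisher
enumeration oracle, and 5,000 background windows. These sizes give Monte
Carlo standard errors comfortably below the margins being checked.

## Worked example

```{r example}
sim <- simulate_dataset(simulation_config(n_positions = 400, seed = 7))
sites <- call_editing_sites(sim$profiles, sim$samples,
                            transcripts = sim$transcripts)
sites
summary(sites)
score_calls(sites, sim$truth, level_min = 0.10, depth_min = 50)[1:3]
```

```{r context}
wins <- site_windows(sites, sim$genome)
neighbor_distribution(wins)
head(sort(trinucleotide_contexts(wins), decreasing = TRUE), 3)
table(vapply(wins, function(w) find_inverted_repeat(w)$arm_length,
             integer(1)))
```

## Known limitations

* The caller consumes pre-aligned base-call data (pileup text); mapping,
  trimming, mate-overlap clipping and germline-variant subtraction are
  upstream concerns.
* The beta-binomial p-values are asymptotic except at low depth; they are
  mildly conservative at three replicates per group (see above).
* Strand assignment from pileup counts alone is usually uninformative for
  paired-end directional data; supply transcript models.
* The stem-loop model scores sequence complementarity only -- no
  thermodynamics, no wobble pairing, no multi-branch structures.
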