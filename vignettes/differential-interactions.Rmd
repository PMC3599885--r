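---
title: "Quantifying condition-dependent chromatin interaction changes at bin resolution"
author: "hicdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condition-dependent chromatin interaction changes at bin resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdyn)
```

## The problem

Hi-C produces paired reads whose two ends mark loci that were physically
close in the nucleus. At megabase resolution, the question this package
addresses is not where individual loops sit, but how the *global*
interaction landscape of a genome reorganizes between two cellular
conditions — for instance a hormone-stimulated versus a control state of
the same cell line. Three quantities carry the analysis:

1. **Interaction frequency** of a bin: the fraction of all genome bins
   with which it has at least one observed contact. Bins whose frequency
   is exceptionally high ("hot regions", conventionally at or above 30%)
   interact with much of the genome; bins at or below 0.5% are "cold".
2. **Observed/expected Z-scores** per bin pair, which put intra- and
   inter-chromosomal contacts on a comparable standardized scale.
3. A bounded **relative ratio** comparing each bin pair's interaction
   strength between the two conditions, which saturates at ±2 for
   contacts present in only one condition and anchors interpretable
   fold changes (see below).

## Model and procedure

### Binning and contact matrices

`bin_genome()` tiles each chromosome with fixed-width windows (default
1 Mb); the last window per chromosome is truncated. Coordinates are
1-based inclusive everywhere in the package; BED exports convert at the
I/O boundary only. `build_contact_matrix()` canonically orders the two
ends of every read pair, removes coordinate-identical duplicates (PCR
artifacts and amplified-segment redundancy), and accumulates a symmetric
count matrix. The bin count is a property of the supplied chromosome
sizes — nothing in the package assumes a particular assembly, and the
exact number of bins a given genome yields depends on which sequences
(sex chromosomes, unplaced contigs) the user includes in the
chrom.sizes input.

### Expected model and Z-scores

The expected count of an intra-chromosomal pair at bin separation $d$ is
the genome-wide mean raw count over all intra-chromosomal pairs at that
separation; the expected count of an inter-chromosomal pair is the
global inter-chromosomal mean. This distance-stratified
observed/expected form is the standard way to remove the dominant
distance decay of contact probability; a `"uniform"` mode (single global
mean) is kept for comparison. For observed cells (raw count > 0) the
ratio count/expected is standardized to a Z-score:

$$Z_{ij} = \frac{r_{ij} - \bar r}{\mathrm{sd}(r)},\qquad r_{ij} = \frac{C_{ij}}{E_{ij}}$$

with the mean and *population* SD taken over the observed cells of the
same contact class — intra and inter standardized separately, because
their ratio scales are not comparable. Unobserved cells carry the
sentinel $Z = 0$ together with an explicit observed mask, so a genuinely
observed cell whose Z happens to be numerically 0 is never confused
with "no interaction". Whether standardization should be genome-wide or
per chromosome is a genuinely open choice; genome-wide was selected so
that hot-region contrasts are measured against a common background, and
the class-wise population is documented as a fixed constant of the
method.

### Interaction frequency and hot/cold regions

`interaction_frequency()` counts each bin's observed partners (the
observed mask, not $Z \neq 0$) and divides by the total bin count. The
self-pair is excluded from the numerator by default while the bin stays
in the denominator; both conventions differ by under one denominator
unit and a flag toggles the choice. `call_regions()` ranks bins at or
above the hot threshold (descending) and at or below the cold threshold
(ascending), breaking ties by genome order so ranks are deterministic.

### The relative ratio

For each cell, each condition contributes an exponential interaction
strength $E = e^{Z}$ when the cell is observed and $E = 0$ otherwise.
The differential statistic is

$$\rho = \frac{E_1 - E_0}{(E_1 + E_0)/2} = 2\,\frac{k - 1}{k + 1},
  \qquad k = E_1/E_0,$$

treated minus control, so positive values are treatment-specific gains.
The denominator must be the average of the *exponential strengths* (not
of the raw Z-scores): only that form reproduces the calibration anchors
— 2-, 5- and 10-fold changes map to 0.67, 1.33 and $18/11$ (displayed
truncated as 1.63), and condition-exclusive contacts map to exactly
$\pm 2$ — and only with $E = 0$ on unobserved cells (rather than
$e^0 = 1$) do pure gains and losses reach the saturation endpoints.
Cells observed in neither condition remain 0 and are flagged excluded.

A **strong** interaction change is a cell with $|\rho| = 2$ whose
observed-condition Z-score exceeds 1 (strict inequality); the four
types are gain/loss crossed with intra/inter. The relaxed criterion —
$|\rho| \ge 2/3$ (a two-fold change, displayed as 0.67) with any
observed Z — is available as `mode = "relaxed"`. The Z threshold is
applied to the largest observed-condition Z-score; for $|\rho| = 2$
exactly one condition is observed, so the two readings coincide.
`gain_loss_profile()` credits each call to both endpoint bins (once if
they coincide); crediting a single anchor would halve the counts without
changing ranks, and the symmetric choice keeps the profile independent
of the arbitrary ordering of the two bins.

### Integration with annotations

* Genes are split by `partition_genes()` into 5 kb upstream of the 5'
  TSS, gene body, and 5 kb downstream *anchored at the TSS* — the
  literal reading of a TSS-referenced partition; anchoring downstream
  at the 3' end instead is a configurable alternative reading, and the
  flank is a parameter.
* `aggregate_signal()` counts track reads per gene part (by read
  midpoint), applies $\log_2(\text{count} + 1)$ — base and pseudocount
  are parameters recorded in the summary — and averages over genes
  whose TSS falls in each bin. Bins without genes are excluded and
  reported; the excluded set depends only on the annotation, so it is
  identical across marks and conditions.
* `enrichment_test()` compares the per-gene values of treated versus
  control for the genes of each interaction type with a **paired**
  t-test (default) or Wilcoxon signed-rank test, paired on gene name.
  The pairing is not optional statistics: the same genes are measured
  in both conditions, and an unpaired test against the between-gene
  baseline variance would be badly conservative. The T sign is positive
  exactly when the treated mean exceeds the control mean. Raw p-values
  are reported (Benjamini–Hochberg adjustment can be applied with
  `p.adjust` on the output).
* `breakpoint_overlap()` counts rearrangement break-points inside hot
  bins and evaluates the uniform-null binomial upper tail in log space,
  so enrichment probabilities far below double underflow remain
  resolved (`log10_p`); a hypergeometric tail is available by flag. The
  choice of tail is a modelling decision — the data are break-point
  *sites*, each of which can fall in any bin independently under the
  null, which is the binomial reading.
* `peaks_per_bin()` assigns peaks by midpoint; `rank_association()` is
  the Spearman correlation between per-bin peak counts and interaction
  frequency. `expression_correlation()` and `de_enrichment_chisq()`
  (2×2 chi-square without continuity correction by default) complete
  the expression-side integration.

## The synthetic study generator

No sequencing data accompany the analysis, so `sim_config()` and the
`simulate_*` generators produce inputs with the statistical structure
the pipeline assumes, at a size where every stage can be exercised in
seconds. The default configuration — chosen once, as the package's
definition of its study conditions — is:

* four chromosomes of 50/45/40/35 Mb at a 1 Mb window (170 bins), so
  that distance decay, chromosome edges and inter-chromosomal sparsity
  all appear without hg-scale matrices;
* ~3,500 expected background pairs per condition: intra-chromosomal
  contact probability $\propto (d+1)^{-\alpha}$ with $\alpha = 1$ (the
  canonical contact-decay scaling), inter-chromosomal background of
  0.05 expected counts per bin pair;
* ten hot bins whose trans-contact rate is multiplied by 15, which
  reproduces the observed contrast between hot regions (interaction
  frequencies in the 30–55% range) and typical bins (~10%) — hot bins
  are implemented as rate multipliers because hot regions are defined
  by genome-wide contact breadth, not by deep contacts at one partner;
* planted strong changes with the composition seen in estrogen-treated
  cells — more gain-intra than loss-intra (9 vs 3), far more loss-inter
  than gain-inter (12 vs 4), total losses exceeding gains — each
  emitting 25 pairs only in its own condition;
* negative binomial tracks (size 8; size → ∞ recovers Poisson) whose
  treated-condition means shift by ±1 log2 unit for genes in
  differential regions, signed like the canonical estrogen response
  (H3K4me3, H3K27me3, H3K9ac, H3K14ac up; H3K9me3 and Pol-II down;
  H3K4me1 flat);
* 800 genes with 15% of bins left gene-free (the gene-desert exclusion
  the signal summaries must handle), peaks coupled to expected
  interaction frequency, 314 break-points entering a hot bin with
  probability 0.22, and expression tables whose cross-condition
  correlation is ~0.99 by construction.

One modelling decision deserves emphasis: **the background architecture
is shared between the two conditions.** Both conditions receive the
identical background pair stream derived from the seed, and they differ
only through the planted condition-specific cells (background is
suppressed at planted cells). Two *independent* sparse Poisson
replicates of the same intensity would disagree by condition-exclusive
cells everywhere, and a saturation statistic like the relative ratio
would flag thousands of spurious "strong changes" — no threshold
recovers a planted truth against that null. Treatment is therefore
modelled as a targeted re-organization of a common architecture. The
flip side is stated plainly: the generator does **not** emulate
replicate-level sampling noise in the contact counts, aneuploid
karyotypes, restriction-fragment structure, or mappability biases.
Passing recovery tests on this generator demonstrates that the
estimator identifies condition-specific re-organization correctly when
it exists; it does not demonstrate robustness to biological replicate
variability, which fixed-threshold calling (as opposed to per-cell
significance testing) cannot address by design.

All generators are pure functions of the configuration: the background
stream is keyed by the seed alone (identical across conditions), and
each annotation stream uses a fixed offset of the seed, so every output
is byte-identical under a fixed configuration.

## Numerical choices and degenerate inputs

* Population (not sample) SD in the Z standardization; if a class's
  ratio SD is 0, its Z-scores are 0 with the observed mask preserved.
* Zero-variance rows in correlation matrices and zero-variance
  expression vectors yield `NA` (undefined), never a silent 0.
* Ranking ties (region calls, top changed regions) break by genome
  order.
* The binomial tail is computed via `pbinom(log.p = TRUE)`; the
  round-trip $k = (2+\rho)/(2-\rho)$ is exact to 1e-12 relative error
  over fold changes within ±6 log units (closer to the ±2 saturation,
  floating-point cancellation dominates, which is a property of the
  statistic's compactification, not of the implementation).
* Empty inputs (no pairs, no peaks, empty call sets, gene sets below
  two members, empty hot sets) return explicitly empty or `NA`-flagged
  results rather than errors, except where the input is malformed.

## Problem sizes used in validation

The package's own validation (the test suite and the acceptance script)
runs the synthetic study at its default 170-bin genome over 20 seeds
for recovery properties (hot-bin ranking, gain/loss precision and
recall, mark-shift T signs) and 50 seeds for the null calibration of
the enrichment tests, with brute-force oracles on genomes of at most 20
bins. These sizes were chosen as the smallest at which the planted
effects are comfortably identifiable by design (see the power reasoning
above), keeping the full suite under half a minute.

## Known limitations

* Fixed-threshold differential calling provides no per-cell error
  control; replicate-aware dispersion modelling is out of scope.
* The expected model is the mean-based observed/expected form; no
  iterative balancing (ICE/KR) is applied, so residual coverage biases
  survive into the Z-scores.
* Interaction frequency counts partners, not contact depth; two bins
  with very different total counts can share a frequency.
* The hypergeometric break-point alternative treats break-points as
  draws of distinct bins, which is only an approximation when several
  break-points share a bin.
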