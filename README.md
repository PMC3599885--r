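# hicdyn

Genome-wide analysis of condition-dependent chromatin-interaction
dynamics from Hi-C read pairs, at bin (e.g. 1 Mb) resolution.

Chromatin architecture reorganizes when cells respond to a stimulus —
for example when a hormone-receptor-positive cell line is treated with
its ligand. `hicdyn` is for analysts who have binned Hi-C data (or raw
read pairs) for two conditions of the same genome and want to answer,
quantitatively: which regions interact with much of the genome ("hot
regions"), which individual bin-pair contacts are gained or lost upon
treatment, and how those changes line up with epigenomic marks,
transcription-factor binding, rearrangement break-points and gene
expression.

## The statistics at the core

For each condition, raw bin-pair counts \(C_{ij}\) are divided by an
expected level \(E_{ij}\) (distance-stratified mean for
intra-chromosomal pairs, global mean for inter-chromosomal pairs) and
the observed cells are standardized per contact class:

\[ Z_{ij} = \frac{C_{ij}/E_{ij} - \bar r}{\mathrm{sd}(r)} \]

Unobserved cells carry a sentinel \(Z = 0\) with an explicit mask. A
bin's **interaction frequency** is the fraction of all bins with which
it has an observed contact; bins at or above 30% are hot, at or below
0.5% cold.

Between conditions, each cell's change is the bounded **relative
ratio** on exponential strengths \(E = e^Z\) (0 when unobserved):

\[ \rho \;=\; \frac{E_1 - E_0}{(E_1 + E_0)/2} \;=\; 2\,\frac{k-1}{k+1},
   \qquad k = E_1/E_0 \]

so a 2-, 5- or 10-fold change maps to 0.67, 1.33 or 1.63, and a contact
present in only one condition saturates at exactly ±2. A **strong
change** is a cell with \(|\rho| = 2\) and observed-condition \(Z > 1\),
classified into gain/loss × intra/inter-chromosomal. Downstream,
gene-part signal aggregation, paired t/Wilcoxon enrichment tests,
Spearman peak–frequency association, a log-space binomial break-point
enrichment test and chi-square differential-expression enrichment
connect the interaction calls to regulation.

Because such studies rarely ship raw pairs, the package includes a
first-class synthetic-study generator (`sim_config()`,
`simulate_pairs()`, `simulate_tracks()`, `simulate_annotations()`)
that emulates distance-decaying contacts, sparse trans background,
boosted hot bins, planted condition-specific gains/losses, shifted
negative-binomial tracks, coupled peaks, enriched break-points and
correlated expression — so the whole pipeline is testable end to end.

## Worked example

```r
library(hicdyn)

cfg <- sim_config(seed = 42)                      # the default synthetic study
fit <- hic_differential(simulate_pairs(cfg, "T0"),
                        simulate_pairs(cfg, "T1"),
                        cfg$genome)
fit
#> Differential chromatin-interaction fit
#>   genome: 170 bins (4 chromosomes, 1e+06 bp window)
#>   pairs retained: T0 3965, T1 3915 (duplicates removed: 0 / 0)
#>   strong differential calls (|ratio| >= 2, Z > 1): 28
#>     gain-intra 9, loss-intra 3, gain-inter 4, loss-inter 12
#>   hot regions (>= 30% at T0): 10; cold (<= 0.5%): 0
```

The 28 strong calls are exactly the condition-specific cells the
generator planted, with the treatment-like composition (few intra
losses, many inter losses). The frequency distribution and the top hot
regions:

```r
frequency_table(fit$freq0)
#>   threshold_pct n_regions
#> 1             1       170
#> 2             5       169
#> 3            10       144
#> 4            20        10
#> 5            30        10
#> 6            40        10
#> 7            50         4
#> 8            60         0

head(fit$regions[fit$regions$call == "hot", ], 3)
#>  bin chrom   start     end frequency_pct call rank
#>  150  chr4 1.4e+07 1.5e+07      56.47059  hot    1
#>  169  chr4 3.3e+07 3.4e+07      52.94118  hot    2
#>   76  chr2 2.5e+07 2.6e+07      51.17647  hot    3
```

The ten bins at or above 30% frequency are the ten boosted hot bins.
Integration with the simulated annotations:

```r
ann <- simulate_annotations(cfg)
breakpoint_overlap(ann$breakpoints, fit$regions, cfg$genome)
#> breakpoint overlap: 91 of 314 in 10 hot bins of 170
#>   (binomial tail p = 1.04e-37, log10 p = -37.0)

expression_correlation(setNames(ann$expression$T0, ann$expression$gene),
                       setNames(ann$expression$T1, ann$expression$gene))$r
#> [1] 0.994
```

91 of 314 break-points fall in hot regions — wildly more than the ~18
expected under a uniform null, hence the vanishing tail probability —
while expression stays essentially unchanged across conditions
(r ≈ 0.99), the signature of structural re-organization without
wholesale transcriptional change. `plot(fit)` draws the per-bin
gained/lost interaction profile along the genome;
`summary(fit)` adds the threshold table, region calls and the regions
with most changes. See the vignette in `vignettes/` for the model,
its assumptions and the generator's design.

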