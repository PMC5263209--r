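# mpqtl — multiparent QTL mapping with founder-probability mixed models

`mpqtl` is an R package for mapping quantitative trait loci in multiparent
recombinant-inbred-line (RIL) populations of the backcross–intercross
type used in barley pre-breeding: four wild donor accessions each crossed
to a recipient cultivar (Morex), backcrossed to the recipient once,
intercrossed pairwise into six subpopulations, and selfed to the F6 by
single seed descent. That pedigree leaves on average 75% of each RIL
genome derived from the recipient and 12.5% from each of its two donors.
The package is aimed at quantitative geneticists who want to analyse (or
simulate and power-check) such designs end to end without external data.

## What it computes

**Founder probabilities.** SNP genotypes are converted into genetic
predictors by a hidden Markov model: for line *i* in cross *k* and locus
*l*, the vector `x_ikl` of posterior probabilities that the line carries
each founder's genome there (3-state forward–backward smoothing per
chromosome, stationary prior 0.75/0.125/0.125, exact zeros for founders
outside the line's cross).

**The genome scan.** A three-stage REML mixed-model analysis of line
means:

    y_ik = mu_k + sum_{c in C} x_ikc' b_c + x_ikl' b_l + e_ik

with fixed cross means `mu_k`, independent random 4-vectors of
wild-founder effects (`b ~ N(0, s2 I4)`, deviations from the recipient)
for the tested locus and every background cofactor in `C`, and
cross-specific residual variances `V(e_ik) = s2_k`. Stage one scans with
no cofactors (simple interval mapping); stage two iteratively adds the
strongest QTL above `-log10(p) = 3.2` as a cofactor and rescans, excluding
cofactors within 10 cM of the tested locus; stage three fits all detected
QTLs jointly and reports shrunken founder effects ± prediction SEs.
Significance is the likelihood-ratio test of `s2_l = 0` against the
boundary-corrected `1/2 chi2_0 + 1/2 chi2_1` mixture. Pairwise epistasis
is tested by adding a random interaction term built from the two loci's
probability columns, Bonferroni-corrected.

**Fine mapping and NIL analysis.** Heterogeneous-inbred-family (HIF)
selection, recombinant screening between flanking markers, EM two-point
recombination fractions (Haldane map function), co-segregation interval
delimitation, VCF hard filtering (QUAL ≥ 30, FS ≤ 30, QD ≥ 2, DP > 4),
gene-origin classification, segregating-interval detection on the genetic
map, candidate shortlisting, and coding-sequence indel effects
(frameshift/premature stop).

**Summaries.** Plot-basis broad-sense heritability from replicated lines
(one-way expected mean squares) and relative trait percentages.

A full generative simulator of the breeding design (`simulate_population()`,
`simulate_phenotypes()`, `simulate_self_progeny()`) provides calibrated
synthetic data for all of the above.

## Worked example

Simulate the study design, infer founder probabilities, scan, and fit the
final model (this is what the shipped demo configuration runs):

```r
library(mpqtl)
cfg <- read_run_config(system.file("extdata", "demo_config.txt",
                                   package = "mpqtl"))
res <- run_pipeline(cfg, "demo_run")
print(res$scan)
print(res$fit)
```

Output (about 90 seconds on one CPU):

```
Multi-QTL scan: 1 QTL(s) at threshold 3.2
  name  locus chromosome position minus_log10_p
 Q7H.1 7H_m28         7H      135      232.7667
Joint founder-effect QTL model (1 QTL, 918 lines)
  Q7H.1   7H  135.0 cM  -log10(p) = 232.8  [7H_m27 | 7H_m29]
    effects vs Morex: HID4 -4.08 +/- 0.41, HID64 -17.52 +/- 0.59,
    HID369 -1.29 +/- 0.45, HID382 -23.46 +/- 0.59 (mm)
```

The demo plants a single awn-length QTL at 133.9 cM on 7H with additive
wild-founder effects (−3.5, −19.0, −1.0, −24.7 mm) relative to the
recipient at heritability 0.75. The scan localizes it to the nearest
marker (135 cM at the demo's 5 cM marker spacing) and the joint model
recovers all four founder effects within ~2 SE; `-log10(p)` is the
mixture-LRT evidence for the founder-effect variance at that locus, far
beyond the 3.2 detection threshold. `demo_run/` also contains the
simulated map, genotypes, phenotypes, truth tables, the scan profile and
the QTL table as TSV, plus a log echoing every configuration value and
stage sub-seed.

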