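---
title: "Multiparent QTL mapping with founder-probability mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparent QTL mapping with founder-probability mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpqtl)
```

## The study system and what the package models

`mpqtl` analyses multiparent recombinant-inbred-line (RIL) populations of
the kind used to map awn length in barley: four wild donor accessions each
crossed to an elite recipient cultivar (Morex), the F1 backcrossed to the
recipient once, the resulting BC1F1 plants intercrossed in all donor pairs,
and each intercross progeny taken through single seed descent (SSD) to the
F6. This pedigree leaves, in expectation, 75% of every RIL genome derived
from the recipient and 12.5% from each of its two donors; the package's
simulator, its hidden-Markov founder-probability model and its mixed-model
scan all encode exactly this structure.

The package has three layers:

1. **`popsim`** — a generative simulator of the breeding design (meioses,
   founder mosaics, SNP genotypes, replicated phenotypes), so every method
   can be exercised and calibrated against a known truth without any
   external data.
2. **Inference** — founder-origin probabilities by HMM smoothing
   (`compute_founder_probs()`), the three-stage REML mixed-model genome
   scan (`scan_sim()`, `scan_mqm()`, `fit_final()`, `test_epistasis()`),
   heterogeneous-inbred-family (HIF) fine mapping (`find_recombinants()`,
   `estimate_two_point_rf()`, `delimit_interval()`), and near-isogenic-line
   (NIL) transcript-variant analysis (`filter_variants()`,
   `classify_gene_origin()`, `detect_segregating_intervals()`,
   `candidate_shortlist()`, `indel_effect()`).
3. **Summaries** — broad-sense heritability from replicated lines
   (`broad_h2()`) and relative trait percentages (`relative_trait()`).

## The mixed model

Let $y_{ik}$ be the line-mean phenotype of RIL $i$ in cross (subpopulation)
$k$, and let $x_{ikl}$ be the vector of posterior probabilities that the
line carries each wild founder's genome at locus $l$. The single-locus
model is

$$y_{ik} = \mu_k + x_{ikl}^{\top}\beta_l + \varepsilon_{ik},
  \qquad \beta_l \sim N(0, \sigma_l^2 I_4),
  \qquad V(\varepsilon_{ik}) = \sigma^2_{\varepsilon,k},$$

with fixed cross means $\mu_k$, a random 4-vector of wild-founder effects
(deviations from the recipient) and cross-specific residual variances. The
multi-QTL scan adds random cofactor terms $x_{ikc}^{\top}\beta_c$ for
already-detected background QTLs, and the final model carries all detected
QTLs jointly.

Restricted maximum likelihood is computed by direct optimization of the
restricted log-likelihood over log-variances (`nlminb`, relative tolerance
1e-10, at most 200 iterations), with fixed effects profiled analytically
inside the objective. Because the covariance is diagonal-plus-low-rank,
$V = D + U\Lambda U^{\top}$, the objective uses the Woodbury identity and
only factorizes matrices of the order of the number of random columns; the
kernel is implemented in C++ (RcppArmadillo). Founder effects are reported
as the shrunken predictions (BLUPs) of $\beta$ with prediction-error
standard errors from the mixed-model equations.

**Significance.** The reported $-\log_{10}(p)$ for a locus comes from
the likelihood-ratio test of $\sigma_l^2 = 0$. The null value lies on the
boundary of the parameter space, so the reference distribution is the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture; a non-positive LRT gives
$p = 1$ exactly, as does a locus whose probability block is constant
across lines (no founder contrast to test). The default detection
threshold is $-\log_{10}(p) = 3.2$ and the cofactor exclusion window is
10 cM; both are `run_config()` parameters.

**Cofactor handling in the iterative scan.** When the locus under test
lies within the exclusion window of a cofactor, that cofactor is dropped
from the model for that test. A consequence is that the profile inside the
window of a selected QTL shows the *same* QTL again; such loci are
therefore not candidates for a new detection. A locus can be selected only
once, and iteration stops when nothing outside the existing QTLs' windows
exceeds the threshold. Ties break deterministically to the lowest
chromosome (map order), then the lowest cM.

**Epistasis.** For each QTL pair the model gains one random interaction
term whose design columns are the elementwise products of the two loci's
wild-founder probability columns (16 columns, one shared variance), tested
by the same mixture LRT and Bonferroni-corrected over pairs.

## Founder probabilities

Per line and chromosome, founder origin is modelled as a three-state chain
(recipient, donor p, donor q) — the full diplotype process collapses well
to this because F6 lines are ~97% homozygous. Parameters
(`hmm_params()`):

| parameter | default | meaning |
|---|---|---|
| `recipient_prior` | 0.75 | stationary probability of the recipient state; donors share the rest equally (pedigree expectation) |
| `map_expansion` | 2 | multiplier from map cM to mosaic transition intensity; selfing-derived RILs accumulate roughly twice the crossovers of one meiosis |
| `genotyping_error` | 0.01 | emission mass on the wrong homozygote |
| `residual_het_rate` | 1/32 | emission mass on a heterozygous call, the expected residual heterozygosity after five selfings |

Transitions over a gap of $d$ cM stay in the current state with
probability $e^{-0.01\,\cdot\,\text{expansion}\,\cdot\,d}$ and otherwise
jump to the stationary prior; this kernel preserves the prior by
construction, so a line with no informative markers returns exactly the
pedigree expectation. Missing calls emit 1 in every state. Posteriors come
from scaled forward–backward smoothing and are embedded in the five-founder
vector with exact zeros for founders outside the line's cross.
`interpolate_to_grid()` inserts silent loci at grid positions and
re-smooths, so off-marker scan positions carry properly interpolated
vectors. The forward–backward code is verified against exhaustive
path-sum enumeration (difference below 1e-10) and against the simulator's
truth (binned posterior calibration within ±0.05).

**Marker-density sensitivity.** The model standard errors condition on the
founder probabilities. On sparse maps (≳5 cM spacing) the residual
founder-assignment uncertainty adds effect-estimate error the SEs cannot
see, which matters for the largest effects; at the study-like density of
~2.5 cM (≈365 informative markers genome-wide) the 2-SE coverage of the
true effects is nominal. Full-scale analyses in the tests and acceptance
script therefore use 2.5 cM spacing.

## The simulator

Meiosis is the Haldane model: crossover counts Poisson(length/100),
uniform positions, no interference, no obligate chiasma; genetic lengths
are in cM on seven 150 cM chromosomes by default. The founder panel codes
the recipient as reference everywhere, with each donor polymorphic at a
marker with probability 0.5 (SNP-chip-like ascertainment). Phenotypes are
generated as cross mean + founder-dose-weighted additive QTL effects +
Gaussian replicate noise; with `heritability_target` set, the residual SD
is solved from the realized genetic variance so that plot-basis
$H^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_E)$ hits the target — the same
convention `broad_h2()` estimates, so recovery is well-posed. The default
study conditions are 6 donor pairs × 153 lines (916-scale), 4 replicates,
$H^2 = 0.75$, and the reference wild-founder effect set
(−3.5, −19.0, −1.0, −24.7 mm) at 133.9 cM on 7H.

What the simulator deliberately does **not** emulate: crossover
interference, sex-specific or expanded genetic maps, segregation
distortion and selection during SSD, genotyping error that is
allele-biased or missing-not-at-random, founder-specific marker
ascertainment, and any polygenic background beyond the specified QTLs.
Passing tests therefore demonstrate correctness of the machinery under the
stated design, not robustness to those real-data features.

## Fine mapping and NIL variant analysis

HIF screening selects lines heterozygous at the target marker
(`select_hif_lines()`); their selfed progeny are screened for recombinants
between two flanking markers, a recombinant being any plant whose 0/1/2
genotype class differs between the flanks (this captures hom↔het
transitions; plants with a missing flank call are counted unscreenable).
Two-point recombination fractions in selfed progeny are estimated by EM
over the ambiguous double-heterozygote class, with Haldane's map function
for cM conversion, clamped at 0.5 with a warning when the counts are only
consistent with free recombination.

`delimit_interval()` places the QTL by co-segregation: a marker
co-segregates when every homozygous recombinant NIL's genotype class at it
matches its phenotype class; the interval is delimited by the nearest
marker on each side that does recombine. This equals the intersection of
the per-recombinant admissible regions (each single-breakpoint recombinant
confines the QTL to one side of its breakpoint), which is how the
brute-force oracle in the tests computes it. Phenotype classes are
assigned by two-sided t-tests against the homozygous reference groups at
α = 0.05; a NIL compatible with none or several classes stays
unclassified.

Variant hard filtering keeps a record iff QUAL ≥ 30, FS ≤ 30.0, QD ≥ 2.0
and DP > 4; "coverage exceeding four reads" is read strictly (DP = 4
fails), and a missing FS/QD passes that single criterion with a log
message. Gene origin is wild iff the gene carries at least one passing
homozygous-alternate SNP (the recipient is the reference genome);
heterozygous-only genes are recipient with a `segregating` flag.
Segregating intervals between a NIL pair are maximal runs of
origin-discordant genes merged across gaps smaller than `gap_tolerance`
(default 1 cM), with boundaries at the outermost discordant genes.
`indel_effect()` classifies insertions by length mod 3 and reports the
first premature stop of the mutated translation (standard genetic code).

## Phenotype summaries

`broad_h2()` uses the one-way expected-mean-squares decomposition on
lines: $\hat\sigma^2_G = \max(0, (MS_{line} - MS_{err})/\bar r)$ with
$\bar r$ the harmonic-mean replicate count, and plot-basis
$H^2 = \hat\sigma^2_G / (\hat\sigma^2_G + MS_{err})$. Whether the study's
printed value is plot- or line-mean-basis is not derivable from the data
description; the plot basis is this package's documented convention,
mirrored exactly by the simulator's calibration. Negative variance
estimates clamp to zero. `relative_trait()` reports group means as
percentages of a reference group (reference = 100), rounded half-up to one
decimal as trait tables conventionally print them.

## Numerical choices and degenerate inputs

* REML: log-variance parametrization bounded in
  $[10^{-8}\,\hat\sigma^2_y,\ 10^{6}\,\hat\sigma^2_y]$; warm starts along
  the scan with the tested-locus variance always restarted away from the
  boundary (a boundary warm start can trap the optimizer at the null); a
  fit that ends below its own null's likelihood is refit cold.
* A Cholesky failure inside the objective returns a large penalty rather
  than an error, so the optimizer backs away from degenerate parameter
  combinations.
* Zero-length chromosomes never recombine; a gamete copies one homolog
  with probability 1/2.
* `fit_final()` refuses QTLs closer than the exclusion window on one
  chromosome (their probability columns are near-collinear) and instructs
  merging.
* Ties and orderings are deterministic everywhere (map order, then cM,
  then detection order), and every pipeline stage derives its sub-seed
  from the master seed, so identical configurations reproduce outputs
  byte-identically.

## Problem sizes used by the tests

Unit tests run on scaled-down populations (typically 1–3 chromosomes of
60–150 cM, 5–10 cM marker spacing, 40–1500 lines, 6–25 replicate
simulations per property) chosen so the whole suite exercises every
stochastic property at meaningful power in about two minutes. The
acceptance checks run one full-scale replicate of the study design (918
RILs, seven 150 cM chromosomes, 2.5 cM markers) plus 20-seed averages for
the recombinant-screen counts. The simulator's defaults are the study
conditions; test scale choices affect only how precisely each property is
measured, never the generative parameters.

## Known limitations

* The founder-probability model is the three-state homozygous
  approximation, not a full inheritance-vector HMM over ordered
  genotypes; residual heterozygosity is absorbed into the emissions.
* No kinship/polygenic term: with many small background QTLs and none of
  them fitted, scan p-values can be anti-conservative.
* Prediction SEs condition on the estimated variance components and on
  the founder probabilities; both understate uncertainty on sparse maps
  (see marker-density note above).
* Differential-expression status enters the candidate shortlist as a
  precomputed boolean per gene; the package does not test expression
  itself.
* `scan_mqm()` scans marker positions by default; use
  `interpolate_to_grid()` for denser scan grids.
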