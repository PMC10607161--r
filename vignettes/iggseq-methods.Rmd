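---
title: "Methods: fraction-aware antibody-coating analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fraction-aware antibody-coating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iggseq)
```

## The measurement model

An antibody-sequencing experiment sorts SYBR-stained stool microbes into
three fractions — 'all' (every SYBR+ event), antibody-bound ('IgG
positive') and unbound ('IgG negative') — and shotgun-sequences each.
`iggseq` models this as a two-stage sampling process:

1. **Sorting.** Each cell of taxon $i$ is coated independently with
   probability $\theta_i$ (per-cell Bernoulli coating). With community
   relative abundances $RA_i$, the bound fraction occupies
   $S^+ = \sum_i RA_i\,\theta_i$ of SYBR+ events and the unbound fraction
   $S^- = 1 - S^+$; the two sizes sum to one exactly before sorter
   non-idealities.
2. **Sequencing.** Reads per fraction are multinomial at fixed depth, with
   compositions $RA_i$ ('all'), $RA_i\theta_i / S^+$ (bound) and
   $RA_i(1-\theta_i)/S^-$ (unbound).

The per-cell Bernoulli assumption is the simplest model consistent with
binary sorter gating; it ignores within-taxon heterogeneity of epitope
display. Counts are multinomial with no taxon-specific genome-size or
whole-genome-amplification bias: amplification bias is real in bench data
but would confound the estimator-recovery tests the generator exists to
support, so it is deliberately out of scope.

## The probability-ratio score

For taxon $i$ in sample $j$, with sorted-fraction relative abundances
$p_{ij}$ (bound) and $n_{ij}$ (unbound),

$$\mathrm{ratio}_{ij} = \log_2\frac{p_{ij}\,S^+_j + c}{n_{ij}\,S^-_j + c}.$$

$p_{ij} S^+_j$ estimates the joint probability that a random SYBR+ cell is
of taxon $i$ *and* antibody-bound, i.e. $RA_{ij}\theta_{ij}$; the
denominator estimates $RA_{ij}(1-\theta_{ij})$. The abundance cancels, so
the score converges to the coating log-odds
$\log_2\bigl(\theta_{ij}/(1-\theta_{ij})\bigr)$ as depth grows and
$c \to 0$ — it measures how much antibody targets a taxon, not how common
the taxon is. Positive scores mean preferential coating.

Key parameters:

* **Pseudocount $c$** (unitless, on the joint-probability scale): 1e-5 for
  species tables, 6e-10 for gene families. It keeps ratios finite when a
  feature is missing from one fraction and damps low-abundance noise; a
  doubly-absent feature scores $\log_2(c/c)=0$, or NA when the caller asks
  for undefined scores (`na_when_absent`), which is how gene families
  lacking a ratio in some sample are identified and dropped.
* **`scale`** (default TRUE): both fraction sizes are divided by the larger
  of the two before use. This leaves the $c \to 0$ ratio untouched (the
  common factor cancels) while putting $c$ on a comparable scale across
  samples whose absolute fraction sizes differ.
* **Fraction sizes** are proportions of SYBR+ events in $[0,1]$;
  percentage inputs are divided by 100 at parse time. The reported bound
  fraction size carries an isotype-control background, which
  `normalise_flow_isotype()` subtracts (flooring at zero) before scoring.

## Filtering rules and their order

The pipeline's stage order is fixed, because filtering order changes
results: total-sum scaling, then detection thresholding, then zeroing
against the 'all' fraction, then scoring, then diversity / functional /
paired statistics.

* Detection is **strictly greater than** the threshold: a relative
  abundance exactly equal to 1e-6 (profiling) or 1e-5 (antibody scoring)
  is removed. The profiling pseudocount 1e-7 is added to every cell,
  zeros included, after thresholding.
* Zeroing is **per sample**: a taxon undetected in one participant's 'all'
  fraction is removed from that participant's sorted fractions only. The
  same rule holds for gene families, where "present in 'all'" means RPK
  $> 0$ (not the 1e-6 threshold; the stricter reading would also remove
  families with real but faint community-level signal).
* Gene families below the threshold in **seven or more** samples are
  discarded (`max_below = 7`, configurable). The alternative reading
  "more than seven" exists in the field; the stricter procedural variant
  is the default.

## Diversity and multivariate choices

Shannon (natural log; base configurable) and inverse Simpson indices are
computed with `vegan::diversity`, and rarefied richness defaults to the
analytic hypergeometric expectation
$\sum_i \bigl[1 - \binom{N-N_i}{d}/\binom{N}{d}\bigr]$
(`vegan::rarefy`) rather than a single random subsample: it is
deterministic and unbiased, and a seeded Monte-Carlo mode exists to
cross-check it. Rarefaction depth defaults to the cohort-wide minimum
across the two sorted fractions, with any per-fraction choice available by
passing a different depth.

Bray–Curtis dissimilarities feed NMDS (`vegan::metaMDS`, monotone
regression) with 20 random starts by default; the best configuration by
Kruskal stress-1 is kept. NMDS finds local optima, so quality claims are
stress-based, never coordinate-based, and the seed is recorded.

CLR transforms are per sample, $\log x_i - \overline{\log x}$; when zeros
are present and no pseudocount is given, half the smallest non-zero value
in the table is added (documented, configurable). PCA (`stats::prcomp`,
centred, unscaled) orders components by variance and fixes signs by making
each component's largest-magnitude loading positive, so results are
deterministic. Patients and controls enter PCA unpaired.

## Paired statistics

Patient–control comparisons use a two-tailed paired t-test. "Evidence for
non-normality" is operationalised as Shapiro–Wilk on the paired
differences at $\alpha = 0.05$, applied only when `auto_log = TRUE` and
all values are positive; the transform decision is recorded in the result.
Zero-variance differences are flagged `degenerate` rather than raising:
identical vectors give $t = 0, p = 1$, constant non-zero differences give
an infinite $t$ with NA $p$. No multiple-testing correction is applied by
default (raw p-values are reported); `stats::p.adjust` can be applied
downstream.

## What the generator emulates — and what it does not

Defaults describe a small paired household study: 5 pairs, 60 taxa,
lognormal abundances ($\sigma = 1.5$), coating probabilities
$\theta \sim \mathrm{Beta}(2,2)$ (no empirical coating distribution is
available, so a symmetric, moderately informative prior was chosen once),
microbial load lognormal around $1.5\times10^{11}$ cells/g (within the
range flow cytometry reports for human stool), read depth $2\times10^5$
per fraction, gating gap 0.05 and isotype background 0.01 — small,
plausible sorter non-idealities that exercise the normalisation paths
without dominating signal. Household members share correlated
log-abundances (correlation 0.9 by default) and a common coating profile;
a patient effect multiplies coating odds by `patient_theta_scale`.

The generator does **not** emulate: rare-taxon tails and open-ended
richness (real stool has hundreds of species at power-law abundances;
synthetic communities are closed at `n_taxa`, so presence proportions run
near 1 rather than the ~0.9 of real data), amplification and genome-size
bias, taxonomic misassignment, strain-level variation, or compositional
zeros from database gaps. Passing tests therefore validate the estimator
and the pipeline's bookkeeping under the stated sampling model — they do
not certify behaviour on real sequencing artefacts.

## Numerical notes

* Ratios are computed as $\log_2(\mathrm{num}) - \log_2(\mathrm{den})$, so
  swapping the fractions negates every score bit-exactly; scale invariance
  to a common factor on both fraction sizes is bit-exact for power-of-two
  factors and holds to IEEE rounding error (~1e-15) otherwise.
* All randomness flows through explicit integer seeds; a cohort seed
  deterministically derives per-pair and per-sample seeds, making fixtures
  bit-reproducible.
* Estimator recovery is validated at depth $10^6$ with $c = 10^{-8}$ on a
  50-taxon community, comparing per-taxon scores with
  $\log_2(\theta/(1-\theta))$ for taxa at $RA \ge 10^{-3}$; at that depth
  the maximum absolute deviation is dominated by multinomial noise on
  low-abundance, extreme-$\theta$ taxa and sits near 0.1. Effect-direction
  and null-calibration checks run 50 and 200 simulated cohorts at reduced
  depth ($2\times10^4$ reads, 40 taxa) — sizes chosen so the full suite
  runs in seconds while keeping Monte-Carlo error well inside the tested
  margins.

## Known limitations

* The score saturates for $\theta$ near 0 or 1 at finite depth: a taxon
  absent from one fraction is bounded by the pseudocount, so extreme
  log-odds are compressed toward $\pm\log_2(x/c)$.
* Per-sample mean probability ratios share a sample-level offset (overall
  IgG reactivity), which is exactly what the paired design tests; per-taxon
  inference across participants needs larger cohorts than the paired
  5-pair design can power.
* QMP columns sum slightly off the microbial load because conversion is
  applied to thresholded, pseudocounted profiles; `renormalise = TRUE`
  restores exact mass conservation when that matters.
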