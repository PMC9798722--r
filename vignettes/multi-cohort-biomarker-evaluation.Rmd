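---
title: "Methods: multi-cohort biomarker evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort biomarker evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamarker)
```

## The problem and the statistical model

A candidate tumor marker is rarely supported by one large series. The
typical evidence base is a handful of public expression cohorts — different
platforms, different countries, group sizes from 3 vs 3 up to 159 vs 4 —
plus, with luck, an in-house protein-level series. metamarker treats this as
a two-layer problem:

1. **Within cohort**, expression is summarized per group as
   (n, mean, SD) on the log2 scale, and the tumor-vs-control contrast is a
   standardized mean difference (SMD). Cohen's *d* divides the mean
   difference by the pooled SD; its large-sample variance is
   `(n1+n0)/(n1 n0) + d²/(2(n1+n0))`. The underlying assumption is
   approximate normality of log2 expression within groups — reasonable for
   microarray and log-transformed RNA-seq abundances, and exactly what the
   generator produces.

2. **Across cohorts**, SMDs are combined by inverse-variance weighting.
   Between-cohort heterogeneity is expected (platforms, populations), so
   the random-effects model with the DerSimonian–Laird moment estimator of
   τ² is selected automatically whenever I² > 50% or the Cochran-Q p-value
   is below 0.05; otherwise the common-effect model is used. Confidence
   intervals use normal quantiles throughout. DL with normal quantiles is
   the classic, non-iterative choice; its small-k anticonservativeness is a
   known limitation (see below).

The same pooling engine drives three other analyses: logit-transformed
sensitivities and specificities of per-cohort 2×2 tables (diagnostic
meta-analysis), Fisher-z transformed correlation coefficients
(`z = atanh r`, `se = 1/sqrt(n-3)`), and the per-gene pooled SMDs used to
confirm screened genes.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| SMD flavor | Cohen's d | – | matches the classic Stata-style workflow this chain mirrors; Hedges g exposed via `correction = "hedges"` for small cohorts |
| model rule | I² > 50% or Q-p < 0.05 | – | conventional heterogeneity trigger for random effects |
| DE thresholds | \|log2FC\| > 1, BH-adj p < 0.05 | log2 units | strict inequalities; a doubling is the usual biological-relevance floor |
| co-expression | \|r\| ≥ 0.3, p < 0.05 | – | weak-to-moderate correlation floor; non-strict on r, strict on p |
| vote count | ≥ 5 cohorts, same direction | cohorts | a gene must replicate in the majority of the nine cohorts |
| ROC cutoff | Youden J, ties to the lower cutoff | expression | maximizes sens + spec − 1; the lower cutoff prefers sensitivity |
| zero cells | +0.5 to all four cells | counts | standard diagnostic-meta continuity correction |
| Fagan pre-test | 0.2 | probability | typical referral-population prevalence used in the motivating analysis |
| IRS | intensity 0–3 × proportion 0–4, mean over 10 fields | score 0–12 | mean aggregation (median available); fields are nominally ten high-power fields |

Two bin-edge decisions are worth making explicit. The printed convention
for the stained-cell proportion ("<10%", "11–50%", ...) leaves 10–11%
unassigned; the implementation uses half-open bins (0, 0.10], (0.10, 0.50],
(0.50, 0.80], (0.80, 1], with exactly zero staining mapping to category 0.
In the median split for survival, samples exactly at the median join the
high group.

## Design choices where the design was genuinely open

**Batch handling.** Cohorts merged across a shared platform keep their
source labels, and `batch_center()` performs gene-wise location adjustment
only: each batch mean is moved to the gene's grand mean. This removes
additive batch offsets — the dominant artifact the generator plants — but
deliberately does not touch scale differences or estimate latent surrogate
variables. It preserves each gene's grand mean exactly and never changes
group proportions.

**Per-gene tests.** The DE screen uses an ordinary per-gene Welch t. At the
simulated group sizes (most informative cohorts have ≥ 8 per group)
variance-moderation would change little; the cost is reduced power in the
3-vs-3 cohorts, which the vote-counting step absorbs by requiring support
in five cohorts rather than all.

**Co-expression across all samples.** Correlations with the target are
computed over tumor and control samples jointly. This means a strongly
differential gene correlates with a differential target partly through the
group contrast itself — which is precisely why the screened CEG and DEG
lists can intersect into non-empty sets A and B.

**Survival hazard ratio.** The primary HR is the Cox partial-likelihood
estimate for the high-vs-low group. The simple log-rank O/E ratio
`(O_h/E_h)/(O_l/E_l)` is also reported (`hr_oe`) but is biased toward 1
for large effects: at a true HR of 4 with near-complete follow-up it
centers near 3, because late risk sets are depleted of high-risk subjects.
Parameter-recovery simulations (true HR 4, n = 200, ~5% censoring) place
the Cox estimate in [3, 5.3] in about 91% of replicates; the O/E ratio
manages 48%. That measurement is what settled the choice.

**Begg's test.** Standardized deviates use the fixed-effect mean and
variance `v_i − 1/Σw`; ties contribute to neither the concordant nor the
discordant count, and the normal deviate applies the continuity correction
`(|P−Q|−1)`. The correction makes the test conservative and the statistic
discrete — which matters when checking its null behavior (below).

**Moses–Littenberg sROC.** The summary ROC is the classic least-squares
line `D = a + bS` with `D = ln DOR` and `S = logit(sens) + logit(FPR)`,
traced over a 1001-point FPR grid and integrated by trapezoid. When all
studies share one operating point, S has no spread and the slope is pinned
to 0, giving the symmetric curve through that point. This is deterministic
and dependency-free; it is not the bivariate/HSROC mixed model, and its AUC
can differ from one for heterogeneous small studies.

## What the generator emulates — and what it does not

`simulation_spec()` defaults describe the study conditions: nine cohorts
with group sizes (159/4, 58/17, 7/4, 3/3, 25/3, 3/3, 25/8, 18/18, 10/6),
1000 genes, a target planted at SMD 3, 50 up- and 50 down-regulated genes
at ±2 log2 units, a 50-gene block sharing a standard-normal latent factor
with the target (loading 0.7, so the block's true all-sample correlation
with a null target is 0.49/1.49 ≈ 0.33), gene-wise per-cohort batch shifts
(SD 0.5), unit residual SD, exponential survival with hazard 0.02/month
quadrupled above the target median and exponential censoring at
0.002/month (~5% censored), and IHC multinomials calibrated to expected
specimen IRS ≈ 6.8 (tumor) and ≈ 2.2 (control) over ten fields.

Emulated features: log-scale approximate normality, wildly unequal group
sizes, additive batch structure, direction-consistent DE across cohorts,
latent-factor co-expression, expression-driven hazards.

Not emulated: count-level sampling noise and mean–variance coupling,
platform-specific probe effects, correlated fields within an IHC specimen
(fields are drawn i.i.d., so simulated specimen IRS variance is smaller
than in real series — visible as a larger IHC SMD than the expression
cohorts'), gene–gene correlation beyond the single latent factor, and
non-proportional hazards. Passing tests therefore demonstrate the
statistical machinery is correct under its stated assumptions, not that
real cohorts satisfy those assumptions.

## Numerical and degenerate-input conventions

- ROC curves place a point at every distinct threshold (positive iff value
  ≥ cutoff); trapezoidal AUC then equals the tie-half-weighted
  Mann–Whitney statistic to machine precision, which the tests assert at
  1e−9.
- A gene constant in both groups gets `p = NA` in the DE screen and can
  never pass; constant genes are skipped (with a warning) in the
  co-expression screen; `|r| = 1` maps to `p = 0` rather than a dividing
  singularity.
- Duplicate gene symbols collapse by arithmetic mean (idempotent);
  symbols are always uppercased at the boundary.
- Batches of size one cannot be centered and are left alone with a
  warning; a singleton subgroup in subgroup pooling is reported as the
  study's own effect and CI rather than "pooled".
- Boundary probabilities (0 or 1) are rejected by the Fagan step; pooled
  sensitivities/specificities stay inside (0,1) by construction after the
  continuity correction.
- All randomness flows from a single integer seed: expression from
  `seed`, IHC from `seed + 1`, survival from `seed + 2`, so each data type
  is reproducible in isolation and the whole pipeline is bit-reproducible.

## Problem sizes used in validation

The test suite sizes its simulations to be informative and quick: SMD
parameter recovery uses 200 replicates of the nine-cohort design with a
planted SMD of 2 (a 10-gene panel suffices, since the pooled SMD depends
only on the target gene); the false-discovery check uses 100 cohorts of
1000 genes at n = 20/20; AUC/Mann–Whitney equivalence uses 100 random
tied instances; enrichment p-values are checked by exact enumeration on
universes of ≤ 15 genes; null-calibration checks use 500 simulations
(log-rank on permuted markers at n = 120; Begg at k = 15). Because the
Begg statistic is discrete, its uniformity is asserted on randomized
p-values against the exact Kendall null distribution, and the reported
continuity-corrected p is separately required not to be anticonservative.
The summary-ROC null/power checks use nine cohorts of 500 + 500 samples:
large enough that in-sample Youden-cutoff optimism — a real small-sample
bias of cutoff selection, worth remembering when reading per-cohort
sensitivities from tiny series — is negligible; the whole-chain check on
the study-sized design (3-vs-3 cohorts included) asserts pooled
sensitivity and specificity ≥ 0.85.

## Known limitations

- DL random-effects CIs with normal quantiles undercover for very few
  studies; with k = 4 cohorts the per-gene confirmation step confirms
  ~10% of null genes instead of the nominal 5% (at the full k = 9 design
  it is ~4%). Hartung–Knapp-type corrections are out of scope.
- The Moses–Littenberg sROC ignores within-study sampling correlation
  between sensitivity and specificity.
- Location-only batch centering cannot remove scale or correlation batch
  artifacts.
- Vote counting treats cohorts symmetrically regardless of size; a 3-vs-3
  cohort and a 58-vs-17 cohort each contribute one vote.
- The IHC generator draws fields independently within a specimen, so
  specimen-level variance is optimistic relative to real tissue series.
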