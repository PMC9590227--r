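---
title: "Measuring the reliability of DNA-methylation predictors across preprocessing pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the reliability of DNA-methylation predictors across preprocessing pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrel)
```

## Motivation and design

Weighted-CpG DNAm predictors inherit every artifact that survives
preprocessing of the raw two-color array intensities. With technical
replicate pairs — the same DNA extraction assayed twice at separate
occasions — the agreement between the pair isolates technical variation,
and the intraclass correlation (ICC) of a predictor's estimates over pairs
scores how well a preprocessing pipeline removes it. `methrel` implements
that evaluation end to end: a synthetic cohort generator with controlled
artifacts, a composable kernel grid, a predictor engine, the ICC family,
and downstream phenotype associations. `run_experiment()` chains the
stages: the replicate subset feeds reliability, a disjoint general subset
feeds associations, and the two are joined by rank aggregation and
ICC-versus-statistic correlations.

## The measurement model

The generator works on a scaled-down Infinium-style manifest (default
2,000 CpG probes rather than hundreds of thousands; every component is
size-agnostic). Per probe $p$ and array $a$, with per-probe lognormal total
signal $S_p$ and per-probe/array lognormal noise:

* **type II** probes read methylated signal in the green channel and
  unmethylated in red:
  $M = S\,\beta'\,m_{a,g} + b_g$, $U = S\,(1-\beta')\,m_{a,r} + b_r$, where
  $\beta' = 0.5 + c_a(\beta - 0.5)$ is a per-array linear compression
  toward 0.5;
* **type I** probes read both alleles in their own channel ($\beta' =
  \beta$), and additionally record an out-of-band (OOB) draw from the
  opposite channel's pure background law;
* **control pairs** measure one fixed target in both channels, making the
  red/green imbalance of each array identifiable;
* **negative controls** are pure background in both channels.

Background $b_c$ is additive truncated-normal (at zero) per channel, with a
per-array log-scale level jitter (`bg_array_sd`); because OOB draws come
from exactly this law, OOB background correction is identifiable and
unbiased. The channel multipliers $m_{a,c}$ collect a red-only dye factor
$e^{\delta_a}$, $\delta_a \sim N(0, \sigma_{dye}^2)$ (so the SD of
control-pair log red/green ratios across arrays equals `dye_bias_sd`),
independent per-level, per-channel batch effects for chip, chip position,
plate and well, and an occasion-wide intensity shift.

Two generator choices deserve emphasis, because they are what makes kernel
effectiveness measurable at all:

* a *fixed* type-II compression affects both arrays of a replicate pair
  identically and cannot create replicate disagreement; real probe-type
  bias varies by array, and the calibration kernel is fitted per array.
  The generator therefore jitters the compression factor per array
  (`type2_compression_sd`, truncated to (0.05, 1]);
* similarly, per-array background *level* variation (`bg_array_sd`) is the
  removable part of the background artifact; the probe-level spread
  (`bg_sd`) is irreducible noise.

Neighbor pairs — one type-I and one type-II probe declared to share the
same true methylation — are enforced in the truth: the type-II member
receives the type-I member's logit-scale profile, including its aging
slope.

Ground-truth methylation uses a three-class (hypo/hemi/hyper) logit-normal
mixture for probe means, stable subject deviations (SD 0.5 logits), and a
designated aging-CpG subset (10% of probes by default) drifting linearly
with age on the logit scale at a mean |slope| of 0.02 logits/year. The
latent aging score is a weighted sum of true betas over aging CpGs; its
drift direction is drawn separately from the slope magnitude so the
zero-slope null remains non-degenerate. Survival follows an exponential
hazard $h = h_0 \exp(\gamma z)$ in the standardized score $z$, censored at
10 years; $h_0 = 0.0163$/year targets the ~15% event rate typical of a
decade of follow-up in a middle-aged cohort (age $\sim N(56.1, 12.4^2)$).

### Default artifact magnitudes

| parameter | default | rationale |
|---|---|---|
| `bg_mean`, `bg_sd` | 500, 50 units | background a modest fraction of the ~5,000-unit median signal |
| `bg_array_sd` | 0.15 (log) | visible array-to-array background drift |
| `dye_bias_sd` | 0.08 (log) | a few percent channel imbalance, typical of two-color arrays |
| `type2_compression` / `_sd` | 0.85 / 0.04 | type-II dynamic range ~15% narrower than type I, mildly array-dependent |
| `batch_sds` (chip, position, plate, well) | 0.090, 0.036, 0.054, 0.036 | calibrated once so batch collectively explains ≈5% of clock-predictor variance, the magnitude reported for population cohorts; chip dominates |
| `occasion_shift_sd` | 0.05 (log) | overall scanner-intensity drift between occasions |

Replicate pairs land on different chips by default (occasions are processed
separately); `replicate_layout = "adjacent"` co-locates them for
sensitivity analyses.

## Preprocessing kernels

Pipelines are ordered choices `bg → dye → norm → beta → probe`, labeled
`bg=?,dye=?,norm=?,probe=?`; the all-`none` spec is the raw pipeline.

* **Background** (`oob`, `neg`): subtract the per-array, per-channel mean of
  the designated background source, flooring at 1 intensity unit.
* **Dye** (`mean`, `relic`): `mean` rescales the red channel so per-array
  control means match; `relic` regresses log green-control on
  log red-control across the control pairs and maps every red measurement
  through the fitted line. The two coincide exactly for a purely
  multiplicative imbalance.
* **Normalization** (`q1`, `q2`, `q3`): quantile normalization via
  `limma::normalizeQuantiles` (reference = mean of sorted columns, average
  ties). The stratification semantics are this package's definitions: `q1`
  normalizes within the four cells {meth, unmeth} × {type I, type II};
  `q2` within {meth, unmeth} pooling types; `q3` pools everything.
* **Beta**: $\beta = M/(M+U+100)$; the offset-100 convention is
  platform-standard.
* **Probe type** (`rcp`): per-array robust regression (bisquare IRLS, max
  50 iterations) of type-I beta on type-II beta over neighbor pairs,
  applied to all type-II betas. The regression is done on the **beta
  scale**, where linear compression is exactly invertible — on noise-free
  pairs the corrected type-II betas equal truth to numerical precision.
  Results are clipped to [0, 1] and the clip count recorded.

Sample QC excludes arrays with >5% of CpGs at detection $p > 0.05$
(detection p-values are upper-tail normal probabilities of total intensity
under the per-array, per-channel negative-control background law) or with
chipwide median log2 (un)methylated intensity below median − 3·MAD of the
array medians.

## Reliability and associations

`icc()` computes all six Shrout–Fleiss forms from the two-way table mean
squares. The significance test is $F = MSR/MSE$ with $(n-1, (n-1)(k-1))$
df (the form used for the consistency family; the one-way forms use
$MSR/MSW$); the report does not depend on which published cohort test was
used since all six forms and CIs are emitted. Confidence intervals follow
the classical F constructions, with the Satterthwaite degrees of freedom
for the absolute-agreement form. Numerical conventions, chosen where the
design was genuinely open:

* negative ICC estimates are reported as computed and flagged, not floored;
* pairs with a missing member are dropped listwise with a log message;
* a zero-total-variance table raises a degenerate-data error rather than
  returning ICC = 1;
* betas are clipped to $[10^{-6}, 1-10^{-6}]$ wherever a logit is taken.

Batch decomposition fits a linear model of the estimate on dummy-encoded
chip/position/plate/well; the collective $R^2$ is reported alongside
*marginal* (single-factor) $R^2$ per factor — marginal rather than
sequential, because the layout makes factors non-orthogonal and sequential
attributions order-dependent. Note that with many factor levels the null
expectation of $R^2$ is roughly (levels)/(arrays), which matters when
interpreting small percentages. `regress_out_batch()` returns residuals
plus the grand mean so replicate ICCs remain well-defined.

Cox mortality models use `survival::coxph` with Efron ties, adjusted for
chronological age by default. Hazard ratios are reported per unit of the
raw predictor, with `standardize = TRUE` switching to per-SD — both
conventions are exposed because neither is universal. Spearman correlations
use average ranks; p-values use the t approximation at $n \ge 10$ and the
exact permutation distribution below that.

Pipeline ranking assigns rank 1 to the highest ICC within each predictor
(average ranks on ties); degenerate cells rank last rather than being
dropped, keeping pipeline counts comparable across predictors.

## What the generator does and does not emulate

The synthetic data reproduce the *structure* that makes replicate-based
evaluation work: paired occasions with independent technical draws, four
separable artifact classes, identifiable controls, and predictors that are
exact on noise-free data. They do not emulate IDAT-level detail, genomic
coordinates, probe-specific hybridization chemistry, cross-reactive or
polymorphic probes, cell-composition heterogeneity between draws, or the
empirical correlation structure of real methylomes. Passing tests therefore
demonstrate that the estimators and kernels are correct and identifiable
under the stated model — not that any particular pipeline is optimal for a
given real cohort.

## Problem sizes

The package's own evaluations run at desk scale, chosen to keep the full
suite interactive: manifests of 400–2,000 probes, 15–50 replicate pairs,
general samples of 80–500, grids of 8–16 pipelines, and Monte-Carlo
ensembles of 20–200 replications (20 seeds for kernel-effect medians, 100
for ICC parameter recovery and Cox coverage, 200 for null calibration).
The two-way ICC recovery check uses fixed occasion offsets whose realized
variance equals the nominal occasion component — with $k = 2$ the occasion
mean square has a single degree of freedom, so randomly redrawn occasion
effects cannot concentrate, while the fixed-offset design recovers the
analytic ratio tightly.

## Known limitations

* The RCP-style calibration assumes an affine type-II/type-I relation on
  the beta scale; strongly nonlinear distortions would need a
  quantile-matching variant.
* RELIC-style dye correction maps red through a log-linear fit; it can
  slightly perturb data that had no bias (the fit is estimated from 85
  noisy pairs), which is why the "no kernel degrades clean data" property
  carries a 0.01 ICC tolerance.
* Composite predictors are supported as two-level compositions (a model
  consuming other models' outputs as columns); deeper nesting is not.
* `k > 2` replicates per sample are accepted by the ICC formulas but the
  test surface targets pairs.
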