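---
title: "Rates, neutral nulls and variability: the methods behind phenorate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rates, neutral nulls and variability: the methods behind phenorate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorate)
```

phenorate asks three questions of a continuous-trait fossil time series —
how fast did the trait evolve, is that pace compatible with neutral
evolution, and is its variability unusual — using the standard machinery of
evolutionary quantitative genetics. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Scales and rates

All divergence work happens on the **mean-standardized natural-log scale**:
the net change between two bins is `ln(z̄_to / z̄_from)`, and the
per-generation rate is that quantity divided by the elapsed generations.
This is the scale on which evolvability is defined and on which the neutral
nulls below are expressed; it requires strictly positive bin means (ECV and
other size traits satisfy this by construction). The companion **haldane**
rate divides the raw mean change by the pooled phenotypic SD of the two
endpoint bins and by the elapsed generations. The pooled SD is the
`(n−1)`-weighted root mean variance of the two endpoint samples — a
per-interval denominator, not a global SD, because each interval's rate
should be standardized by the variation present at its own endpoints. Bins
with `n = 1` may carry a missing SD; they are excluded from haldane-scale
work but remain usable on the mean-standardized scale.

Ages are stored as given (years or generations before present, oldest bin
first, since divergence is reckoned ancestor → descendant); the years →
generations conversion is real-valued division by the generation time (29
years per generation by default for *Homo*), never floored.

## Mode classification by rate–interval scaling

For every ordered pair of usable bins (all pairwise intervals, not just
adjacent ones — the regression needs a spread of interval lengths) the
absolute rate is regressed, log10 against log10 interval, by ordinary least
squares. The slope separates modes of evolution:

* a sustained directional trend gives rates independent of the interval —
  slope **0**;
* an unbiased random walk accumulates displacement like `√t`, so the rate
  falls as `t^(−1/2)` — slope **−1/2**;
* stasis keeps the net difference bounded regardless of elapsed time —
  slope **−1**.

Zero rates are dropped before taking logs (their count is reported); the
mode call is the anchor slope contained in the 95% confidence interval when
exactly one of {0, −0.5, −1} is contained, otherwise `ambiguous`. When the
fit is numerically exact (residual SD below 1e-10, as with noise-free
synthetic lineages) the interval degenerates to a point and classification
falls back to nearest-anchor matching within `classify_tolerance`
(default 0.05).

Two caveats are worth stating plainly. First, the pairwise rates share bins
and are therefore correlated, so the OLS confidence interval understates
the replicate-to-replicate variability of the slope. Second, and as a
consequence, the mode call from a *single* random-walk lineage is
unreliable: across replicate random walks the slope estimate is centred on
−0.5 but scatters with an SD of roughly 0.2, so per-lineage calls spread
over `random_walk`, `ambiguous` and the neighbouring anchors. The package's
tests therefore assert per-replicate recovery only for the noise-free
directional and stasis regimes, and assert the *mean* slope (over 200
replicates) for the random walk. Treat a single-lineage mode call as
descriptive, not inferential.

## Neutral null models

Two nulls give the variance of the among-lineage distribution of
evolutionary outcomes on the log-mean scale after `t` generations:

* **constant-heritability drift**: `σ²_Bμ = e·t/N_e`, with evolvability
  `e` (additive genetic variance over squared mean; default 0.009, a
  human-brain-size figure) and effective size `N_e` (default 5000).
  Divergence by drift is larger when the population is small or the trait
  more evolvable.
* **mutation–drift equilibrium**: `σ²_Bμ = k·σ²_m·t`, with the
  mean-square standardized mutational variance `σ²_m` (default 4e-6, the
  order observed for mass and body-composition traits in mice) and an
  accumulation constant `k`. Published treatments differ in the constant
  they adopt, so `k` is an explicit, always-reported parameter; the default
  `k = 2` corresponds to between-lineage divergence accruing at twice the
  mutational variance per generation. Mutation–drift equilibrium typically
  predicts faster neutral divergence than constant-heritability drift.

An observed divergence is standardized to `z = D/σ_Bμ` and assigned a
normal tail probability. The default is two-tailed, `2·Φ̄(|z|)` capped at
1, since the neutral outcome distribution is symmetric; the one-tailed
option reports the upper tail of the *signed* z, `Φ̄(z)`. The signed
convention is what makes the one-tailed test calibrated: under the
symmetric null it rejects at exactly α, which the package verifies by
simulation (2,000 lineages generated under the drift null; rejection rate
within the binomial 95% band of 5%). For positive z the two conventions
coincide, and the two-tailed p is exactly twice the one-tailed p.
p-values are reported at full precision with no significance stars.

## Selection gradients

The univariate, evolvability-standardized response equation says the
per-generation mean-standardized response to selection is `Δz̄_μ = e·β_μ`.
Rearranged, `β_μ = Δz̄_μ / e` converts an observed rate into the sustained
directional-selection gradient required to produce it in the absence of
drift; β is on the scale where 1 equals the strength of selection on
fitness itself. `required_beta_over_interval()` composes the log-mean
divergence of an interval, its generations, and this rearrangement.
Converting a haldane rate to the mean-standardized scale requires a
phenotypic CV (`Δz̄_μ ≈ h · CV_p`); that CV is always an explicit input,
never inferred.

## Coefficient-of-variation inference

CVs are stored as proportions and rendered as percent in output (one unit
convention internally avoids the classic percent/proportion bug). The
small-sample correction multiplies by `(1 + 1/(4n))`; because fossil
samples are tiny, the correction is applied by default when `n < 30`, and
the correction state is always recorded. The **pooled within-sex CV**
divides the `(n−1)`-weighted within-sex SD by the sample-size-weighted
grand mean, removing the contribution of sexual dimorphism; unknown-sex
specimens are excluded with a reported count, never imputed.

Differences of CVs are reported in percentage points with either a
**percentile bootstrap** interval (the default; each group resampled
independently with replacement, 10,000 resamples by default, seeded and
exactly reproducible; resamples with non-positive means are redrawn, capped
at 100 passes) or a **normal asymptotic** interval using
`var(CV) ≈ CV²(0.5 + CV²)/n` per sample, variances summed. The bootstrap
is the default because it makes no distributional assumption at the tiny n
typical of fossil groups; the package's coverage check (1,000 lognormal
simulations with true ΔCV = 0 at n = 30 per group, 1,000 resamples per
interval) verifies 95% intervals cover within ±2 percentage points of
nominal. Percentile intervals at n = 30 tend to sit at the low edge of
that band — a known mild undercoverage of the percentile method.

Comparative placement uses the empirical percentile of the focal CV among
per-species CVs, with the midpoint convention for ties
(`100·(#below + #tied/2)/n`): a focal value above every species scores
100, below every species 0, and tied at the median of an odd-sized set 50.

## The synthetic-data generator

Trait dynamics are simulated **directly on the log-mean scale** as a
population-level diffusion — not by individual-based Wright–Fisher
reproduction — because the nulls being tested are phrased as
among-population variance formulas on that scale and because testing needs
thousands of replicate lineages per second. Regimes: `neutral_drift`
(increments of variance `e/N_e` per generation, so the replicate variance
of the final log-mean is `e·t/N_e` by construction), `directional`
(deterministic step `e·β` plus drift; `N_e = Inf` disables drift),
`mutation_drift` (increment variance `k·σ²_m`), and `stasis` (independent
mean-zero perturbations about a fixed value). The stasis perturbation SD
(`stasis_sd`, default 0.02 log units, ~2% fluctuation of the mean) and the
starting mean (`start_mean`, default 900 trait units, an early-*Homo*-like
ECV in cc) are generator choices the regime definitions leave open.

Fossil sampling places bins at evenly spaced generations and draws
individuals lognormally about the bin mean (positivity plus a natural CV
parameterization), with a two-sex structure (female mean scaled so the
expected overall mean matches the path under the given dimorphism ratio
and sex ratio) and optional multiplicative lognormal measurement error.
One global seed drives everything, with a derived sub-stream separating
trajectory noise from sampling noise, so each stage is independently
bit-reproducible.

What the generator does **not** emulate: time-varying `N_e` or `e`,
selection that fluctuates or tracks a moving optimum, age-mixing within
bins, dating error on bin ages, taphonomic size bias, and phylogenetic
non-independence among the species of the comparative CV table (species
are drawn i.i.d.). Passing tests therefore demonstrate internal
consistency of the estimators under their own generating assumptions, not
robustness to these real-data complications.

## Numerical choices and degenerate inputs

* Bins with `n = 1` carry `NA` SDs; they are rejected at read time if an
  SD is claimed, and skipped by haldane-scale rate work.
* `lri_fit()` requires ≥ 3 positive-rate pairs and declines (with an
  explanatory message at the command level) otherwise — e.g. for a
  constant series, whose rates are all zero.
* The exact-fit fallback threshold for the LRI interval is a residual SD
  of 1e-10; ties in anchor containment yield `ambiguous` rather than an
  arbitrary pick.
* Bootstrap intervals warn if the percentile interval fails to bracket the
  point estimate (possible in principle with extreme skew).
* Validation errors from the CSV readers always name the offending row and
  column; non-numeric cells are never silently coerced.

## Problem sizes

The test suite and the reproduction script use: 2,000 lineages of
`t = 7.4e4` generations for drift-test calibration; 200 directional
lineages (`β = 0.002`, `N_e = 10⁶`, `t = 10⁴`, two bins of 30 individuals
at within-population CV 0.10) for gradient recovery; 200 lineages per
regime (`t = 5000`, 20 bins) for LRI slope recovery; 2,000 replicates for
the drift-variance moment check; and 1,000 lognormal simulations (n = 30
per group, 1,000 bootstrap resamples each) for ΔCV coverage. These sizes
put Monte-Carlo error comfortably inside each check's tolerance while
keeping a full run to seconds.

## Known limitations

Single-lineage LRI mode calls are descriptive (see above). The neutrality
tests condition on externally supplied `e`, `N_e` and `t` — uncertainty in
those parameters is not propagated. The comparative CV analysis treats
species values as independent; a phylogenetically informed treatment is
out of scope. And the selection-gradient estimates inherit the upward bias
of rates reckoned in absolute terms over coarse intervals: they are best
read as bounds on the strength of sustained selection, not point
estimates of it.
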