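---
title: "Methods: modelling livestock food-security vulnerability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling livestock food-security vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livevuln)
```

## The vulnerability framework

Vulnerability analysis treats the harm a system may suffer as the joint
outcome of three elements: **sensitivity** (how strongly the system depends
on the threatened resource), **exposure** (how much change the system will
actually experience) and **adaptive capacity** (how well it can respond).
`livevuln` applies this framework to national livestock-based food
security: sensitivity is a nation's nutritional reliance on home-produced
grazing-animal products and its current food-security status; exposure is
the projected change in climate and population; adaptive capacity collects
health, economic and governance strength.

The model is deliberately static and relative. It ranks nations against
each other within one cohort at one time slice; it does not forecast
absolute outcomes, and it does not feed exposure back into sensitivity or
adaptive capacity (a dynamic coupling would demand quantitative knowledge
of how governance or wealth respond to climate and population change that
simply does not exist at the global scale — the robustness grid below is
the honest substitute).

## From raw indicators to scores

**Scaling.** Every indicator is scaled linearly to [0, 1] across the
cohort: `(x − min)/(max − min)`, so the lowest observed value maps to 0 and
the highest to 1. Values are *not* normalised to a distribution — the true
spread in the raw values is allowed to shape the final scores. The scale
is therefore cohort-relative: adding or removing a nation can move every
score. Constant indicators have no information at this scale and raise a
zero-range error rather than a silent `0/0`.

**Polarity.** Some indicators point against their construct (life
expectancy raises adaptive capacity; prevalence of food inadequacy raises
sensitivity). Each configured indicator carries a `higher`/`lower`
polarity flag; `lower` reverses the scaled score (`1 − s`) so that a higher
score always means more of the index construct. Polarity lives in the
declarative category configuration, not in code.

**Category reduction.** Indicators are grouped into subject categories,
and each category is collapsed to its single most representative member:
all members are inter-correlated with Spearman rank correlation (midranks
on ties, pairwise-complete observations) and the member with the largest
mean |ρ| against the others is retained. Absolute correlation is used
because an indicator that inversely tracks its category is just as
informative as one that tracks it directly; rank correlation makes the
choice invariant to any strictly monotone re-expression of a member. Exact
ties — unavoidable in a two-member category, where the matrix is symmetric
— are broken by configuration order (first listed wins) and reported. The
six World Bank governance indicators are handled by this same rule, so the
governance category contributes one representative measure.

**The climate composite.** Climate change enters as a single value per
nation: `cc = |Δt| · |Δp| · w`, the product of the absolute projected
temperature change (°C), the absolute projected precipitation change
(native units) and the percentage of the population affected by droughts,
flooding and extreme weather. Magnitudes are used because a large change
in either direction stresses forage and livestock systems; the composite
is symmetric in the sign of both deltas. Being purely multiplicative, a
nation with `w = 0` scores zero however large its projected change — the
package keeps this behaviour (it is the composite's definition) but
reports such nations.

**Supporting conversions.** Herd sizes are compared across species through
livestock units (`Σ count × coefficient`, reference cow = 1.0,
sheep = 0.15; the default coefficient table is overridable by CSV).
Self-sufficiency is `(production − exports)/(production − exports +
imports)`; when re-exports push exports above production the ratio is
clamped to 0 with a warning, and a non-positive denominator with
non-negative net production (no supply at all) is treated as undefined and
the nation flagged missing.

**Missing data.** The default policy is listwise exclusion — a nation
missing any minimal-model indicator is dropped, mirroring the exclusion of
nations absent from either source data bank — with category-median
imputation available as a configuration switch. Validation is report-only
and never mutates the table.

## Index composition and the two models

The three indices are plain component averages, each rescaled to [0, 1]
over the cohort:

* `S = (ss + fs + nc)/3`
* `E = (cc + pg)/2`
* `AC = (he + ec + gv)/3`

The **additive** model scores raw vulnerability `V = S + E − AC` and
rescales it to [0, 1]. Because the rescaling is affine-invariant, any
combination `a(S + E − AC) + b` with `a > 0` — including the
"average-of-three-contributions" form `(S + E + (1 − AC))/3` — yields the
identical rescaled score and ranking; the package tests this invariance
explicitly. The additive form lets an extreme value in one index be offset
by the others.

The **multiplicative** model is `V = S · E · (1 − AC)` by default, so an
extreme value in any one index dominates the product. The exact
multiplicative form is a genuine design choice: adaptive capacity must
*reduce* vulnerability, which `(1 − AC)` does on the same [0, 1] scale; a
ratio alternative `S · E / (AC + ε)` (ε > 0 guards the zero-capacity
denominator, default 0.01) is available in the configuration. Both are
rescaled, so the two forms differ only in ordering. The package's
additive reconstruction is validated against the published 30-nation score
table; no printed numbers exist that would discriminate between
multiplicative forms, so that choice is documented rather than validated.

**Ranks** use the minimum-tie convention (tied nations share the smaller,
i.e. more vulnerable, rank) and ties are reported; rescaling is
order-preserving, so ranks from raw and rescaled scores coincide.

**Scenario variants.** To isolate each exposure driver, the model is
re-run with the other component held constant. "Held constant" is itself
underdetermined; the default policy replaces the held component with its
cohort mean, so it contributes no between-nation variance while exposure
stays on the combined model's scale. A `drop` policy (exposure becomes the
varying component alone) is available for sensitivity checks — with
min-max rescaling the two policies give identical rankings, which is why
cohort-mean is a safe default.

**Aggregation.** Group summaries weight nation scores by population before
averaging, so small nations do not contribute disproportionately to a
regional mean. Percentile extremes use `k = ceiling(fraction · n)` — the
only rule under which the tenth percentile of a 148-nation cohort yields
15 nations per extreme. Model agreement is assessed with Wilcoxon
signed-rank tests on the paired scores (zero differences dropped and
counted, exact p-value for n ≤ 15 without ties, normal approximation with
correction otherwise), and indicator influence with Spearman correlation
against the vulnerability score at α = 0.05; both delegate to R's standard
implementations and are cross-checked in the test suite against exhaustive
sign-enumeration and rank-formula oracles.

## The robustness grid

Sensitivity and adaptive capacity rest on historical data; their future
values are unknown. The grid analysis varies each nation's S and AC from
−100% to +100% of their main-model values in 10% steps — 21 levels per
axis, 441 combinations — recomputes vulnerability with exposure at its
projected level, and summarises each cell by the median across nations of
the percent change from baseline.

Two numerical choices matter here:

* **Baseline anchoring.** Percent change is computed on raw vulnerability
  against the unperturbed baseline, with no per-cell rescaling. Min-max
  rescaling is affine-invariant, so rescaling within each cell would
  cancel any uniform cohort-wide perturbation exactly and force the whole
  grid to zero — anchoring to the baseline is the only reading under which
  the analysis can show an effect.
* **Near-zero baselines.** A nation whose baseline vulnerability is ~0
  turns percent change into a division by ~0. Nations with |rescaled
  baseline score| below a floor (default 0.01 — i.e. the bottom of the
  cohort scale) are excluded from every cell's median and counted; the
  exclusion set is fixed across cells so medians remain comparable.

Perturbed scores are clamped to [0, 1] (clamping is counted), and
perturbations apply to the composite S and AC indices, not to their
component indicators — it is the index scores that are being stress-tested.
The origin cell is identically 0%, and for nations with positive baselines
the median change is monotone increasing in the S offset and decreasing in
the AC offset; both properties are tested.

## What the synthetic generator emulates

`generate_nations()` draws cohorts with the structure the analysis
assumes, with full knowledge of the latent truth:

* three latent indices per nation on the normal scale, with latent
  adaptive capacity negatively correlated with sensitivity (default −0.4,
  matching the observed pattern that highly sensitive nations tend to have
  little capacity to adapt);
* eight categories whose members are Gaussian-copula draws around a
  category factor: member = `(c + τe)/√(1 + τ²)`, factor
  `c = (z + σu)/√(1 + σ²)` with `σ = noise_sd` (default 0.05). τ is set
  from the target intra-category Spearman correlation (default 0.8) via
  the normal-score relation `ρ_P = 2 sin(πρ_S/6)`, so the achieved member
  correlation tracks the target (tested to ±0.1 at n ≥ 100);
* monotone marginal transforms into plausible native units: a [0, 1]
  self-sufficiency ratio, percentage prevalences, a °C warming delta, a
  mixed-sign precipitation delta (mm), an affected-population share, a
  population-growth percentage that can be negative (the European
  pattern), a years-scale life expectancy, a log-scale GDP and a bounded
  governance estimate; one health member is generated with `lower`
  polarity to exercise the reversal path;
* group labels drawn with the frequencies of the 148-nation cohort
  (7 regions at 17/47/24/13/2/5/40, income 28/39/42/39, status 36/77/35)
  and ordinally tied to latent adaptive capacity, a food-deficit flag more
  likely at low capacity, and log-normal populations (meanlog 16, sdlog
  1.5 — median around nine million people).

When `noise_sd = 0` the generator switches all noise off and emits exact
monotone transforms of the latent indices. This is a deliberate reading of
"zero observation noise": it makes the pipeline's recovered ranking equal
the latent ordering *exactly*, which pins down the whole scoring path
(residual intra-category jitter would break that identity, so the
correlation target is honoured only when noise is present). The stored
truth ordering is computed by running the package's own composition on the
noiseless indicators; because sums of per-axis monotone transforms do not
commute with coordinate-wise monotone maps, an ordering defined directly
on the latent normals would not be exactly recoverable even without noise,
and exact recovery is the property worth testing. The per-index truth
values (`s_true` etc.) are the normal CDF of the latent draws and are
rank-identical to the recovered indices at zero noise.

What the generator does **not** emulate: the marginal distributions of
real FAOSTAT/World Bank indicators, spatial dependence between neighbouring
nations, reporting gaps correlated with poverty, or the 76-indicator
redundancy structure the full (non-minimal) model draws on. Passing tests
on synthetic cohorts therefore demonstrate that the pipeline recovers the
structure it assumes — not that real data satisfy those assumptions.

At the default study conditions (n = 100, noise 0.05, ρ = 0.8) the
recovered vulnerability ordering rank-correlates with the latent ordering
at ρ ≥ 0.9; a 24-seed simulation put the observed range at 0.91–0.97
before the threshold was frozen into the tests.

## Validation against the published cohort

The only printed per-nation numeric surface is the index-score table of
the 30 most- and least-vulnerable nations, shipped as `table2_fixture()`.
Feeding its (S, E, AC) triples through the additive model reproduces every
printed vulnerability score within ±0.02 — the band implied by 2-decimal
rounding of three inputs — with the cohort maximum (Kenya) rescaling to
exactly 1.00. Ordering is checked pairwise among the 15 most vulnerable
nations for every pair whose printed scores differ by more than 0.02: two
nations that print identical scores (both 0.76) can legitimately swap
under reconstruction, and the check is designed not to over-claim
precision the inputs do not carry. The component category scores and the
full 148-nation cohort are not printed, so the scenario variants and group
ranks are validated structurally on synthetic data instead.

## Problem sizes and run times

The shipped tests run cohorts of 40–200 nations and the full 441-cell grid
(a few seconds in total); the acceptance checks use the 30-nation
published cohort and seeded 100- and 148-nation synthetic cohorts. These
sizes were chosen because every property being tested — scaling, ranking,
recovery, monotonicity — is already fully expressed at a few dozen
nations; the pipeline itself is vectorised and handles cohorts orders of
magnitude larger without change.

## Known limitations

* Scores are cohort-relative; they cannot be compared across cohorts or
  years without re-scaling, and a zero score means "least in this cohort",
  not "invulnerable".
* The climate composite's multiplicative form silences large projected
  changes wherever the historical extreme-weather share is zero.
* Equal component weighting within each index is an assumption, not an
  estimate; the grid analysis probes uncertainty in the index *levels*,
  not in the weights.
* The multiplicative model's exact form is unverifiable against printed
  numbers; conclusions that depend on the distinction between its product
  and ratio variants should be treated cautiously.
* The generator's recovery guarantees say nothing about biases from
  non-random missingness in real indicator tables.
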