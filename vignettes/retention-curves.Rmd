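---
title: "Fitting and classifying retention curves: models, decisions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting and classifying retention curves: models, decisions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forgetcurve)
```

## The problem

A century of memory research has produced thousands of retention series:
a group of people learns some material, and the proportion they can still
recall, recognize, or relearn with savings is measured after several
retention delays. `forgetcurve` implements a meta-analytic pipeline over
such series: fit a small family of two-parameter forgetting curves to each
data set, decide which pattern each data set follows, summarize how
prevalent each pattern is across a corpus, and ask which study
characteristics (materials, delays, test type, design, ...) make one
pattern more likely than another.

## The five function families

Each family maps a delay $t$ (always in seconds) to a proportion remembered
$M$ through a scale parameter $a$ and a rate parameter $b$:

| family | equation |
|---|---|
| logarithmic | $M = a - b\,\ln t$ |
| power | $M = a\,t^{b}$ |
| exponential-power | $M = a\,e^{-b\sqrt{t}}$ |
| hyperbolic-power | $M = 1/(a + b\sqrt{t})$ |
| linear | $M = b\,t + a$ |

The exponential-power and hyperbolic-power families are the classic
"square root of time" variants: the exponential in $\sqrt t$ is a special
case of the Weibull, and the hyperbola in $\sqrt t$ has mostly appeared in
animal work. Logarithmic and linear curves eventually predict negative
retention, so predictions are truncated into $[0,1]$; we apply the same
truncation to every family for uniformity (`evaluate_curve(..., clamp =
TRUE)`).

**Clamping is not used inside fitting.** Whether the original analyses
clamped predictions during estimation is unknowable from the outside; we
fit against the raw formula so that the boundary cannot hide residual
structure, and treat the boundary as a prediction-time constraint only.
This is the package's own resolution of a genuinely open choice; anyone
wanting the other convention can clamp the predictions and recompute
`r_squared()` directly.

## Fitting

Logarithmic and linear curves are linear in their parameters and are
solved in closed form by ordinary least squares of $M$ on $\ln t$ and on
$t$. The other three families are fitted by Levenberg–Marquardt nonlinear
least squares (`minpack.lm::nls.lm`) minimizing
$\sum_i (M_i - f(t_i))^2$ **in proportion space**. Fitting every family in
the same residual space is what makes the per-family $r^2$ values
comparable; fitting each family in its own linearizing space would bias
the model comparison toward whichever transform most compresses the
residuals.

Starting values come from each family's linearizing transform (log–log
regression for power; $\ln M$ on $\sqrt t$ for exponential-power; $1/M$ on
$\sqrt t$ for hyperbolic-power, with proportions floored at $10^{-6}$ for
the transform only), expanded into a $3 \times 3$ grid of $\pm 50\%$
perturbations. Because three-to-ten-point series can be highly
non-monotone, a few data-scaled coarse candidates are added: for power and
exponential-power the model is linear in $a$ at fixed $b$, so $b$ is
profiled over a grid with the optimal $a$ in closed form; the hyperbolic
family gets a small $25 \times 25$ lattice with its positivity constraint
$a + b\sqrt t > 0$ enforced by an infinite-penalty guard. The best
converged solution by SSE wins; if no start converges, the best candidate
is reported with `converged = FALSE`. A property test checks the fitter
against an independent dense-lattice oracle on a hundred random series.

Fit quality is always $r^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ about the
observed mean, on the untransformed proportion scale; it can be negative
when a fit does worse than the mean. Data sets with zero observed variance
are never fitted — they are stable by definition and are routed through
net-change classification.

`best_fit()` takes the family with maximal $r^2$; ties within $10^{-10}$
fall back to the fixed reporting order (logarithmic, power,
exponential-power, hyperbolic-power, linear) and are flagged.

## Classification

`categorize()` applies three rules in order:

1. **Stable**: if the net change — the proportion at the longest delay
   minus the proportion at the shortest — lies in the closed band
   $[-.01, .01]$, the data set is `no_net_change`. No fit is consulted.
   Net change is evaluated on the observed values, not on smoothed fits;
   the sum of successive interval-to-interval changes telescopes to the
   same number.
2. **Increasing**: a net gain beyond the band is `increasing` (a linear
   fit is attached for typical-curve rendering).
3. **Loss**: otherwise the data set is labeled with its best-fitting
   family when that fit reaches $r^2 \ge .5$, and `removed` when it does
   not.

The `.5` trimming threshold is a configurable default; it sits roughly two
within-corpus standard deviations below the mean best fit in the corpora
this rule was developed for. Stable and increasing data sets are never
removed, whatever their fit quality: they carry information about when
memory does *not* decay, which is part of what the prevalence analysis is
for. Lowering the threshold can only move data sets from removed to
retained, never the reverse — a monotonicity the tests assert.

## Prevalence

`weighted_category_distribution()` weights each retained data set by its
amount of data (sample size × observations per participant) so that a
three-person pilot does not count as much as a thousand-observation study.
"Amount of observations" could also be read as per-participant
observations; both weightings are available, and the amount-of-data
reading is the default. Typical curves per category use the element-wise
median of the winning $a$ and $b$ (median initial memory for stable data
sets), plotted on a log-spaced grid from 1 second to 68 years — the
longest retention interval represented in the corpora this package
targets.

## Characteristics analyses

Thirteen numeric study characteristics are screened for collinearity at
$|r| \ge .70$. The documented reduction drops the retention range,
shortest and average intervals (all nearly collinear with the longest
interval), and the degree of learning (collinear with complexity),
leaving nine predictors; a greedy mode is available for other corpora.
Delays span ten orders of magnitude, so interval predictors are
$\log_{10}$-scaled before the group analyses (toggleable —
`log_longest_ri` in `pipeline_config()`).

Per-factor one-way ANOVAs report $F$, $p$, and partial eta squared
($SS_B/(SS_B+SS_W)$); factors at $p < .10$ get all pairwise Tukey
contrasts with the studentized-range-adjusted $p$, the contrast $t$, and
Cohen's $d$ from the pooled within-pair SD. Adjusted $p < .10$ is labeled
"marginal" in reports. One-vs-rest logistic regressions are fitted per
category on z-scored predictors (so the reported $z$ statistics are
scale-free); perfect separation falls back to a lightly ridge-penalized
fit whose coefficients are reported without $z$ or $p$. Because the
one-vs-rest fits are independent, their predicted probabilities need not
sum to one across categories.

The guide tree is a plain gain-ratio (C4.5-family) classifier with
configurable depth and leaf size, exported as indented rules and JSON. It
is a guide, not a reference implementation of any particular C4.5
codebase.

## The synthetic-data generator

`generate_corpus()` draws retention series with known generating category
and parameters. Trajectories are constructed by choosing the proportion
remembered at the shortest and longest delays and solving the family's two
parameters exactly through those endpoints; every family is monotone
between its endpoints, so noise-free curves stay inside $[0,1]$ by
construction. Defaults: initial memory centered near .72 (higher for
exponential-power, lower for increasing data sets), net drops of .15–.5
for loss curves, rises of .1–.3 for increasing ones, 3–10 log-jittered
intervals spanning two to four-and-a-half decades of seconds, with the
longest interval category-shifted (longer for linear, stable, and
increasing data sets). Covariates are drawn with category-conditional
shifts — simpler materials and single exposures for power, distractor
tasks and high initial memory for exponential-power, and so on — so the
characteristic analyses have real signal to recover.

Noise is additive Gaussian on the proportion scale, clamped into $[0,1]$,
chosen for transparency. Two deliberate deviations from full realism:

* **Stable data sets condition their noise on staying stable.** The
  stable category is defined observationally (|last − first| ≤ .01), so
  the generator rejects noise draws that break the band. Without this,
  independent noise of sd .01 flips about half of truly flat series out
  of the band and "ground truth" would be meaningless for an
  observationally defined class.
* Real proportions are binomial, participants are heterogeneous, and real
  corpora mix delays, designs, and measures far more wildly than the
  generator does. Passing recovery tests therefore show that the pipeline
  recovers what the generator planted — not that any particular empirical
  corpus is classified correctly.

## What recovery can and cannot show

At observation noise sd .01 with five intervals, linear, stable, and
increasing data sets are recovered essentially always, and the
logarithmic/power pair is recovered as a *pair* (>99%) while confusing
its two members with each other at a substantial rate — their fitted
qualities correlate near .99 on the same corpora. The exponential-power
and hyperbolic-power families are at least as collinear (their fit
qualities also correlate near .99, a number the acceptance script
computes), and they confuse each other at roughly a one-in-five rate at
realistic net drops; separating them reliably requires net drops beyond
about .4, which are rarer in practice. This is an intrinsic property of
the function families on short series, not an optimizer artifact: on the
synthetic corpora the fitted true-family SSE is never worse than the SSE
at the generating parameters. Consumers of the classification should
treat logarithmic/power and exponential-power/hyperbolic-power as pairs
unless the data are unusually long and deep.

## Numerical choices and degenerate inputs

* Zero first delays ("immediate" tests) are replaced by .01 s
  (`fixed_epsilon`) or by an estimate of the true test delay, 30 s by
  default (`estimate`), before fitting; several families are undefined at
  $t = 0$.
* Zero-variance series are classified (stable) without fitting;
  $r^2$ is undefined there and the fitter refuses them.
* The hyperbolic denominator is guarded: parameter vectors with
  $a + b\sqrt t \le 0$ anywhere on the data get infinite SSE during
  fitting, and unclamped evaluation raises a domain error.
* The stability band is closed, and tests exercise the exact boundary
  with binary-exact band values to keep floating point out of the
  equality.
* Ties in `best_fit()` are broken by the fixed reporting order and
  flagged rather than silently resolved.

## Problem sizes

The bundled analysis scripts and the acceptance script use a 500-data-set
corpus at noise sd .01 with five intervals per series; property tests use
a hundred random 3–6-point series against the lattice oracle, 200
replicates per family for parameter-recovery bias, and 1,000 label
shuffles for the ANOVA null. These sizes give stable Monte-Carlo estimates
(binomial SE below 2 points on the recovery rates) while keeping a full
run in the tens of seconds.

## Known limitations

* Only two-parameter families are fitted. The three-parameter
  exponential-power generalization $M = a\,e^{-b\,t^{-c}}$ is out of
  scope.
* Model comparison is raw $r^2$ only — no AIC/BIC, no within-data-set
  weighting.
* The trimming threshold is not re-derived per corpus; the trim report
  gives the diagnostics needed to revisit it.
* The guide tree makes no claim of matching any specific C4.5
  implementation's output.
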