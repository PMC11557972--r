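---
title: "Methods: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apisomnia)
```

This vignette documents the statistical models behind `apisomnia`, the
generative model of the synthetic-experiment module, the numerical choices
made where several were defensible, and what the test suite does and does
not establish about real video-scored data.

## The observation model

The unit of data is a scored cage-hour: during the first five minutes of
each hour an observer counts bees alive, bees asleep (all three sleep
markers — antennal immobility, non-continuously pulsating abdomen, leg
immobility — held through the window, with a 30 s grace period after a
nestmate contact), contacts received by sleeping bees, and sleepers in the
lower half of the cage. Hours run 0-based from experiment onset over a
half-open grid `[0, 120)`; the "fourth day" is `[72, 96)` and later
thresholds (79 h for the sleep models, 90 h for the disruptor analyses)
live on the same axis.

Percent asleep is defined over **alive** bees, `100 * n_sleeping / n_alive`,
not over the starting count. Scoring conventions in the field do not settle
this; we track survival separately (`percent_alive`) and keep the sleep
proportion conditional on being alive, so a dying cage does not look
progressively sleepier or more awake by attrition alone. An extinct cage
(no bees alive) reports 0% asleep and is flagged rather than dropped.

## Period estimation

For a series $y(t)$ the period is estimated by harmonic regression over a
dense candidate grid, by default $P \in [20, 28]$ h in 0.05 h steps:

$$y(t) = \mu + \beta_s \sin(2\pi t / P) + \beta_c \cos(2\pi t / P) + \varepsilon(t).$$

$\hat\tau$ maximizes the harmonic power, i.e. minimizes the residual sum of
squares over $P$. Two numerical points deserve note:

* **Power, not coefficient amplitude.** With 120 hourly samples the record
  covers a non-integer number of cycles for almost every candidate period,
  and the raw coefficient amplitude $\sqrt{\beta_s^2+\beta_c^2}$ then peaks
  slightly off the true period (spectral leakage: on a pure noiseless 24 h
  cosine the amplitude-argmax lands at 23.85 h). The power criterion
  recovers that cosine exactly, and the two criteria agree on noisy series.
* **Sub-grid refinement.** After the grid search the period is polished by
  one-dimensional continuous optimization of the RSS within one grid step
  of the grid optimum. Refinement is skipped when the grid optimum already
  fits to machine precision, so exact synthetic fixtures remain exact.
* **Why not an FFT.** A discrete Fourier transform of a 120 h record has
  bins at 120/k h — 30, 24, 20, ... — far too coarse to resolve free-running
  periods in the plausible 20–26 h range.

Amplitude ties across grid points are broken toward the candidate nearest
24 h, then toward the shorter period. A series is flagged *arrhythmic* when
the fitted amplitude is below $k$ times the residual SD at the chosen period
($k = 1$ by default); a constant series gets the flag and an `NA` period
sentinel instead of an error. The acrophase is reported in $[0, \tau)$; a
pure time translation of a series changes only the acrophase, never the
period or amplitude.

`estimate_period()` returns a classed `rhythm_fit` object with `print`,
`summary`, `coef`, `predict`, `fitted`, `residuals`, and `plot` methods, the
idiom R users expect from a fitting function.

## Alignment to the entrained control

Alignment is measured by subtracting each experimental cage's percent-asleep
curve from its light:dark control **paired by replicate index**
(`control − condition`; only signs depend on the direction, magnitudes do
not). The pairing rule is by index because no cohort metadata exists in the
observation table; any other stable pairing would serve as well for the
group-level contrasts. Over the day-4 window the signed and absolute
difference curves are integrated by the trapezoid rule; the absolute area
guards against positive and negative excursions cancelling.

The "midpoint peak" of a curve in a window is not standard; we define it as
the temporal midpoint of the longest contiguous run above half the smoothed
range (3 h centered moving average, edge windows shrunk to the available
points), with run ties broken by higher mean height and then earlier time.
This definition is robust on plateaued curves, where a raw argmax is noise.
The peak distance between a condition and its control propagates an `NA`
sentinel when either window is flat. Peaks whose half-max runs touch the
window boundary are truncated by it, so distances near the window edge are
compressed; the generative acrophase default keeps day-4 peaks inside the
window for the parameters simulated here.

## Group-level inference

**Mixed models.** `rm_mixed_model()` fits
`response ~ treatment * time + (1 | cage)` by REML via `lme4`, with F tests
per fixed term using **Satterthwaite** denominator degrees of freedom
(`lmerTest`); the approximation in use is recorded in the result, and a
residual-df fallback is applied if Satterthwaite degenerates. Cage ids are
globally unique, so the random intercept is implicitly nested within
treatment. Responses: the log-transformed sleep proportion
(`log(p + offset)` with offset `1/(2 max n_alive)` — half of the smallest
possible count increment — so zero counts stay finite; the transform is
monotone, so ranks are unchanged), the lower-half proportion among
sleepers, and contacts per sleeping bee. A constant response returns a
zero-F table flagged singular instead of erroring, as does a zero cage
variance.

**Wilcoxon rank-sum.** Exact two-sided p by full enumeration of all
$\binom{n_1+n_2}{n_1}$ labelings of the pooled midranks (valid under ties)
for combined $n \le 12$, and a tie-corrected, continuity-corrected normal
approximation above that; the path taken is recorded. The switch point is
where enumeration is still instantaneous and the two paths agree to within
0.02 in p.

**Survival.** Percent alive at 120 h per cage, compared across the three
conditions by a tie-corrected Kruskal–Wallis test with a $\chi^2_{k-1}$
reference. Complete ties return $H = 0$, $p = 1$ directly. With three
replicates per condition the statistic is highly discrete: exhaustive
enumeration of all 1680 rank partitions shows the true size of a nominal
5% chi-square cutoff is about 1% without ties, so the test is conservative
at this design size — p-values near 0.05 should be read accordingly.

**Light gradient.** A pooled-variance two-sample t-test
(df $= n_1+n_2-2$), the form consistent with 28 df for 15 readings per cage
section, plus the top/bottom fold ratio of means (scale-invariant).

## The synthetic-experiment generator

`simulate_cage()` draws one cage's series from a damped-cosine model of the
expected proportion asleep,

$$p(t) = \text{baseline} + A(t)\cos\!\big(2\pi (t - \text{phase}_0)/\tau_{\text{eff}}(t)\big),$$

clipped to $[0,1]$, with $\tau_{\text{eff}}(t) = \tau + \text{drift}\cdot t/24$
under constant light only, and $A(t) = A_0(1-\text{decay})^{t/24}$ under both
constant conditions (free-running rhythms damp without a zeitgeber) but not
under the entrained control. Counts are then: deaths binomial per alive bee
per hour; sleepers binomial over alive bees at $p(t)$; disturbance contacts
Poisson with mean `n_sleeping × rate`, the rate switching to its elevated
constant-light value from 90 h; lower-half sleepers binomial over sleepers.
One draw per hour mirrors the 5-minute-per-hour sampling scheme — there is
no continuous-time behavior model, no per-bee trajectories, and no light
physics.

Defaults are the study conditions: 3 cages per condition, 23 bees per cage,
120 h; $\tau$ = 24.0 h (LD, DD) and 24.5 h with 0.25 h/day drift (LL).
Parameters the study design leaves open were fixed once at values a
chronobiologist would call realistic and are not tuned thereafter:
mesor 0.35 and amplitude 0.25 (bees asleep roughly 10–60% of the time over
the cycle), amplitude decay 0.10/day, acrophase 18 h (mid-dark under a
lights-on-at-0 cycle), mortality hazard 0.001 per bee-hour (≈ 11% five-day
mortality), contact rates 0.31 and 1.09 per sleeping bee per window (the
reported dark and light group means used as generative rates), and
lower-half probabilities 0.5 (LD/DD) versus 0.8 (LL). Periods outside the
plausible 20–26 h free-running range are accepted with a warning.

Per-cage sub-seeds are `seed + stride(condition) + replicate` with fixed
strides (LD 10000, DD 20000, LL 30000), so adding replicates or conditions
never reshuffles existing cages, and identical seeds give bit-identical
output.

**What passing tests show — and don't.** The generator reproduces the
statistical skeleton the analysis assumes: circadian counts with binomial
noise, monotone mortality, condition-specific drift and contact rates. It
deliberately omits cage-level random effects (every cage in a condition
shares one mean curve), cohort effects, within-hour behavioral dependence,
and entrainment transients. Parameter-recovery and directional tests
therefore validate the estimators under the assumed model, not the
biological claims on real data. One consequence surfaces in the calibration
checks: under a null where all arms share identical parameters, the common
circadian waveform is not representable by the mixed model's linear-time
fixed effects, so it inflates the residual variance while leaving
between-arm slope contrasts untouched — the interaction F test is
conservative by construction there (the acceptance suite measures its
rejection rate alongside the survival test's), and the nominal-5% criterion
is not met from below. Adding a cage-level random slope or harmonic fixed
effects would change the model contract, so it is reported rather than
"fixed".

## Problem sizes

The shipped checks use 50 simulated cages for period recovery at the
entrained period plus 20 per free-running value, 50 experiments for the
directional day-4 contrasts, and 200 experiments for the null calibration
of the group tests; all complete in well under a minute each on a single
core. These sizes give binomial 95% bands of a few percentage points on the
reported rates, which is the precision at which the claims are stated.

## Known limitations

* Period estimation assumes a single sinusoidal component; ultradian or
  multi-component rhythms are out of scope.
* The alive-bee denominator for percent asleep is a convention, not an
  observation-level fact; with heavy mortality the series becomes noisy as
  the denominator shrinks, and an extinct cage contributes flagged zeros.
* Mixed-model denominator df are approximations (Satterthwaite, or residual
  on fallback); exact reproduction of df from other software's conventions
  is not claimed.
* The day-4 peak metrics inherit the window: peaks drifting past the window
  edge truncate, compressing distances.
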