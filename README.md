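# apisomnia

Circadian sleep-rhythm analysis for caged honey bee (*Apis mellifera*)
experiments.

Artificial light at night can reach honey bee foragers whenever colonies
beard, swarm, or nest near constant illumination. This package analyzes
hourly ethogram-style sleep observations of caged foragers kept under
constant light (LL), constant dark (DD), or a 12 h:12 h light:dark control
(LD) for five days: how rhythmic their sleep is, how well each free-running
condition stays aligned with the entrained control, and whether light brings
behavioral sleep disruptors (jostling by awake nestmates, displacement to
the darker lower cage half) or mortality.

It is written for chronobiologists and behavioral ecologists who score
sleep from video — a bee counts as asleep when it keeps antennal immobility,
a non-continuously pulsating abdomen, and leg immobility through the first
five minutes of each hour — and record, per cage-hour: bees alive, bees
asleep, disturbance contacts received by sleepers, and sleepers in the lower
half of the cage.

## The core methods

**Period estimation.** For a cage's hourly percent-asleep series y(t), the
free-running period τ is found by harmonic regression over a dense grid of
candidate periods P ∈ [20, 28] h (0.05 h steps):

    y(t) = μ + β_s sin(2πt/P) + β_c cos(2πt/P) + ε(t)

τ is the period maximizing the harmonic power (minimizing the residual sum
of squares), refined by continuous optimization within one grid step;
amplitude = √(β_s² + β_c²), and the acrophase follows from atan2(β_s, β_c).
A series whose amplitude falls below the residual SD is flagged arrhythmic.

**Alignment to the control.** Each LL and DD cage is paired by replicate
index with its LD control; the difference curve Δ(t) = control(t) − cond(t)
is integrated (trapezoid) over the fourth experimental day, hours [72, 96),
both signed and in absolute value, and the distance between half-max
"midpoint peaks" of the two curves is reported. Consistent periods keep
day-4 areas small; a drifting period makes the curves fall out of phase and
the areas grow.

**Group inference.** Log-transformed sleep proportions are modeled with
repeated-measures mixed models (REML): treatment, time and their interaction
as fixed effects, cage as a random intercept, Satterthwaite denominator df.
Alignment metrics are compared with an exact-enumeration Wilcoxon rank-sum
test, light levels with a pooled-variance t-test, and survival at 120 h with
a tie-corrected Kruskal–Wallis test.

**Synthetic experiments.** `simulate_experiment()` generates full
three-condition experiments (3 cages/condition, 23 bees/cage, 120 h) from a
damped-cosine proportion-asleep model with condition-specific period and,
under LL, a period that lengthens by 0.25 h per elapsed day, plus binomial
sleep counts, per-bee mortality, Poisson disturbance contacts, and
light-dependent vertical position preference.

## Worked example

```r
library(apisomnia)

obs    <- simulate_experiment(sim_config(seed = 42))
series <- to_sleep_series(obs)

estimate_period(series[["LL_1"]])
#> Harmonic regression period fit
#>   cage LL_1 (LL, replicate 1)
#>   tau = 25.48 h, amplitude = 19.49%, acrophase = 18.05 h, mesor = 33.73%
```

The constant-light cage free-runs long (25.5 h against the generative
24.5 h plus drift), with a damped amplitude; the LD control recovers
tau = 23.87 h. Day-4 alignment against the LD control:

```r
align_to_control(series)
#>      condition replicate_index auc_day4 abs_auc_day4 peak_distance
#> DD_1        DD               1   -13.53          210           2.0
#> DD_2        DD               2     2.81          243           2.5
#> DD_3        DD               3    16.88          322           1.0
#> LL_1        LL               1    25.11          386           3.0
#> LL_2        LL               2    76.90          391           3.0
#> LL_3        LL               3     6.93          319           0.0
```

LL cages show larger absolute day-4 areas (here 319–391 %·h vs 210–322 %·h
for DD) and larger peak shifts: their drifting period pulls them out of
phase with the entrained control. Disturbance contacts after 90 h
(`disturbance_summary(obs)`) average 1.16 per sleeping bee per 5-min window
under LL versus 0.31 under DD (3.7-fold), and the cage light gradient from
the bundled synthetic readings (`compare_light_levels()`) is 6.7-fold,
t(28) = 502.3. Survival at 120 h does not differ here
(Kruskal–Wallis H = 1.25, df = 2, p = 0.54).

`run_pipeline(pipeline_config(sim = sim_config(seed = 42)))` runs all of the
above plus the mixed models, writes tidy CSVs, a median ± MAD sleep-curve
figure, and a machine-readable manifest that reproduces every CSV
byte-identically.

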