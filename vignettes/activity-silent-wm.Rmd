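---
title: "Models and methods: activity-silent working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: activity-silent working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(silentwm)
```

This vignette is the package's own account of the science it implements: the
attractor-network model of conscious and non-conscious working-memory
maintenance, the behavioral mixture estimator, the circular-linear correlation
and decoding statistics, and the design decisions taken where the published
description leaves the implementation open.

## The scientific question

In a delayed-response task, observers remember the location of a briefly
flashed target (1 of 20 positions on a circle) through a masked presentation
and a seconds-long delay. Strikingly, locations reported as *unseen* can still
be reproduced above chance after the delay — working memory without
consciousness. The candidate mechanism is *activity-silent* maintenance:
rather than persistent delay firing, the memory lives in slowly decaying
synaptic variables and can be reawakened by a non-specific read-out signal.

## The network model

`cann_params()`, `build_schedule()` and `run_network()` implement a
one-dimensional continuous attractor network of `N = 100` rate neurons with
preferred angles on `[-pi, pi)`, augmented with short-term synaptic
facilitation and depression on the recurrent connections and a single
inhibitory pool.

State variables per neuron: the synaptic current `h_E`, release probability
`u` (facilitation; baseline `U`, decay `tau_f = 4 s`), available resource `x`
(depression; baseline 1, recovery `tau_d = 0.3 s`), plus the scalar
inhibitory current `h_I`. Firing rates are `R(h) = alpha * log(1 + exp(h /
alpha))`. The recurrent drive is the ring integral of the truncated-cosine
kernel times the effective efficacy `u * x * R_E`, discretized as
`rho * sum_j J[i, j] (u x R)_j * dtheta` with `dtheta = 2 pi / N`.

All printed constants are used as published: `tau = 0.008 s`, `J1 = 12`,
`J0 = 1`, `B = 2.2`, `J_EI = 1.9`, `J_IE = 1.8`, `I_b = -0.1`, `delta1 = 0.3`,
`delta2 = 9`, `alpha = 1.5`, `tau_f = 4 s`, `tau_d = 0.3 s`, `N = 100`. Three
quantities are *not* fixed by the published description and were decided here:

* **`U = 0.3`** (facilitation increment / baseline release probability): a
  standard value in the short-term-plasticity literature; exposed in
  `cann_params()`.
* **`dt = 1 ms`**: explicit Euler steps; `dt < tau` is enforced. See
  "Numerical behavior" below — the integration step is effectively part of
  the model configuration for this system.
* **`rho`** (neuronal density): only identifiable jointly with the kernel
  scale. It was calibrated once against the model's own headline phenomenon —
  the critical mask amplitude near 62 Hz — giving
  `rho = 0.07275 * N / (2 * pi)`, i.e. `rho * dtheta = 0.07275`, with the
  target's Gaussian spatial profile kept at its default width of 0.3 rad.
  Neither value was revisited afterwards.

### Noise

The current equation contains a background noise term (`delta1 * xi1`, always
on in the `continuous` mode) and a stimulus noise term (`delta2 * xi2`, only
while an external input is on; the `input_only` mode keeps just this term).
Both enter the dynamics *as noise currents inside the rate equation*,
alongside `I_b` and `I_e`: the per-step increment is `(dt / tau) * delta *
xi` with `xi` i.i.d. standard normal per neuron and step. The alternative —
treating `delta * xi` as the increment of a Wiener process, which multiplies
the per-step contribution by `1/sqrt(dt)` — makes the stimulus noise two
orders of magnitude larger than the mask amplitudes it perturbs, erases the
dependence of the maintenance regime on the mask, and cannot reproduce the
near-even regime split at the critical amplitude; the current reading
reproduces it under both noise modes, which is itself a property the model is
supposed to have. This is a deliberate interpretation of an underdetermined
description and the single most consequential numerical choice in the
package.

### Phenomenology and regime classification

At the calibrated coupling the network has no persistent bump attractor.
Delay-period memory manifests as discrete population spikes: brief (~tens of
ms) reignitions of the target assembly fuelled by the facilitation trace,
quenched by resource depletion and pooled inhibition. A trial is classified
`reactivating` if its delay-period peak rate exceeds a threshold at least
once, and `silent` otherwise (`classify_regime()`):

* threshold: the scale-free midpoint between the baseline rate `gain(I_b)`
  and the peak rate evoked during target presentation on a noiseless
  reference trial (`reactivation_threshold()`); overridable in Hz;
* delay window: 50 ms after mask offset (excluding the offset transient) to
  recall onset.

The recalled location is the population-vector angle of the time-averaged
rates during the recall pulse (`population_vector_readout()`), flagged
invalid when the normalized resultant is below 0.05 (no coherent bump).
`find_critical_mask()` brackets and bisects the noiseless
reactivating-to-silent transition; `regime_profile()` verifies the
single-switch assumption on a grid.

In silent trials the recall pulse reignites the bump at the stored location
because `u` decays with `tau_f = 4 s` and is still elevated at the target
after a 3 s delay, while `x` has long recovered — memory carried exclusively
by the synaptic variables. Freezing `u` and `x` (`freeze_stp = TRUE`)
abolishes both spontaneous and evoked reactivation, which the test suite
checks.

### Numerical behavior and limitations

The population-spike regime is a hard test for any explicit integrator. Two
properties deserve explicit statement:

* **Smooth trajectories converge.** On sub-ignition trials (all inputs below
  the flare threshold) halving `dt` changes the delay-period trace by under
  2% in relative L2 norm; the suite asserts this on a fixed reference trial.
* **Flare trains do not converge trajectory-wise.** Spike timing depends
  sensitively on the state at ignition, so traces at `dt` and `dt/2` decorrelate
  after the first flare, and the location of the critical mask amplitude
  itself shifts with the resolution. The calibrated `(rho, dt)` pair is
  therefore a joint configuration; changing `dt` re-opens the calibration.

Other known limitations: the per-regime error histograms both peak at the
true location, but the relative dispersion of the two regimes depends on the
noise mode and amplitude — with continuous noise, reactivating trials can
accumulate drift across successive flares and end up *less* accurate than
silent trials. The model also omits the distractor stimulus and any multi-item
load, and the rates during flares (hundreds of Hz) should be read as
population-level event amplitudes, not single-neuron firing rates.

## The behavioral mixture model

`wm_mixture()` decomposes a 20-bin histogram of signed position errors into
uniform guessing and a concentrated true-memory distribution:
`D(n) = p/N + (1 - p) d(n)`, `d` supported on `|n| <= a = 2`. The estimator
uses only the outside bins for `p̂` (15 of 20 bins at `a = 2`), so a uniform
histogram gives exactly 1 and a fully concentrated one exactly 0; `d̂` is the
guessing-floor-subtracted inside distribution, negatives zeroed,
renormalized; precision is its SD (positions; ×18 for degrees). Decisions
taken here:

* offsets use the convention `((response - target + 10) mod 20) - 10`, bins
  `-10 ... +9`; the asymmetric `-10` bin lies outside `[-2, 2]`, so it only
  ever contributes to the guessing estimate;
* finite samples can push `p̂` outside `[0, 1]`; it is clamped with a warning
  (the bound holds only in expectation);
* fits require at least 5 trials, mirroring the minimum-cell rule used for
  per-visibility analyses;
* eligibility: a Pearson χ² test of the correct/incorrect split against the
  25% chance rate, one-sided in effect (above-chance direction required).

`gen_behavior()` draws from exactly this family — guesses are uniform,
true-memory errors follow a discretized truncated Gaussian on `-2 ... 2`
(`offset_distribution()`; note the realized SD is below the nominal Gaussian
SD as it approaches the truncation) — so estimator recovery on generated data
is a closed-loop check, which is how the tests use it (mean `|p̂ - p| < 0.03`
at n = 2000 across the `p × sigma` grid).

## Circular-linear correlation

`circ_linear_r()` combines the two linear correlations of a signal with
`sin(theta)` and `cos(theta)`:
`rho² = (r_xs² + r_xc² - 2 r_xs r_xc r_sc) / (1 - r_sc²)` — the multiple
correlation of the signal on the two regressors, validated in the tests
against an explicit least-squares fit to 1e-10. It is invariant to affine
transforms of the signal and global rotations of the angles. `circ_map()`
computes the channels × time map plus an empirical baseline: the mean map
over label permutations (default 1000), with *the same* trial permutations
applied to all cells so the null preserves the spatial covariance of the
data; `delta_rho` is the map minus this null mean. `window_average()` reports
means over the a-priori windows (0.1–0.3 s, 0.3–0.6 s, 0.6–1.55 s,
1.55–2.53 s).

## Decoding

`temporal_generalization()` and `cross_generalize()` implement the
multivariate pipeline: per training fold and training time, univariate ANOVA
F selection of the top 50% of channels (ties broken by index; degenerate
features rank last), z-scoring with training statistics, inverse-frequency
class weights, and a linear max-margin decoder (`e1071`, cost fixed at 1 for
determinism — no per-fold tuning). Categorical decoders output signed
distances to the hyperplane, scored by midrank AUC per fold and averaged;
circular decoders are paired sine/cosine support-vector regressions with
`atan2` reconstruction, predictions pooled over folds and scored as
`pi/2 - mean |wrapped error|`. Cross-condition generalization trains within
the usual fold loop, applies every fold's decoder to the entire second epoch
set and averages the predictions before scoring. An optional baseline
correction subtracts, per training time, the mean score over test times in
the −200 to −50 ms window; it is off by default since its published form is
not fully specified. Fold construction stratifies circular labels over the 20
discrete positions (2 folds, so every position appears in both when counts
permit).

No quantity computed from test trials ever enters fitting; the suite verifies
this with a shuffle test (mean AUC within 0.02 of 0.5 over 50 label-shuffled
synthetic runs).

## Synthetic epochs

`gen_epochs()` emulates the *statistical structure the analyses assume*:
i.i.d. Gaussian sensor noise plus (a) a fixed category topography added to
one class inside a time window and (b) fixed sine/cosine topographies scaled
by the trial angle inside per-class windows (e.g. a sustained "seen" code and
a transient "unseen" one), with optional trial-wise amplitude jitter, a 250 Hz
default time axis and ground truth recorded for assertions. It deliberately
does **not** model oscillatory content, sensor covariance, forward-model
geometry or autocorrelated noise, so passing tests demonstrate correctness of
the analysis chain on its own assumptions, not performance on real
recordings.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is bit-reproducible
given it; `run_pipeline()` derives recorded child seeds per stage and stamps
outputs with an MD5 hash of the configuration. The sizes used by the checks
are package choices balancing statistical resolution against desk-scale
runtimes: the acceptance script simulates 4000 noisy trials for the regime
split (binomial SE ±0.8 points) and ~6 noiseless trials for the bisection;
the test suite uses 2000 noisy trials for the same split, 100 random
instances for the correlation oracle, 100 replicates per cell for mixture
recovery, 400 trials for the chance-level AUC and 50 runs for the
no-leakage check.
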