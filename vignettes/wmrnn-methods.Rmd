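---
title: "Working-memory RNNs: model, training, and bump-attractor diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working-memory RNNs: model, training, and bump-attractor diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

wmrnn trains continuous-time leaky firing-rate recurrent networks on
spatial delayed-response tasks and asks a mechanistic question: does the
trained network maintain the memorandum the way bump-attractor models of
prefrontal cortex do — as a localized, slowly drifting peak of activity
over a ring of tuned units whose position at the end of the delay
determines behavior? The package provides the task generator, the network
and its training loop, behavioral scoring, and the unit-level statistics
whose joint pattern is diagnostic of that mechanism.

## The model

Each of the $N$ recurrent units carries a nonnegative activity $r_i$
evolving as

$$\tau \frac{dr}{dt} = -r + f\!\left(W_{rec}\, r + W_{in}\, u + b +
\sqrt{2\tau\sigma_{rec}^2}\,\xi\right),$$

with $f(x) = \log(1 + e^x)$ (Softplus) and $\xi$ unit-variance white
noise. Outputs read the state through a logistic:
$z = g(W_{out}\, r)$, $g(x) = 1/(1+e^{-x})$.

Fixed constants, with defaults:

| constant | meaning | default |
|---|---|---|
| $\tau$ | membrane time constant | 100 ms |
| $dt$ | simulation step | 20 ms |
| $\sigma_{rec}$ | recurrent noise strength | 0.05 |
| $N$ | recurrent units | 256 (128 in the desk-scale runs) |

**Discretization.** The continuous equation is integrated by forward
Euler with $\alpha = dt/\tau$:
$r \leftarrow (1-\alpha) r + \alpha f(\cdot + \sigma_{rec}\sqrt{2/\alpha}\,\varepsilon)$,
$\varepsilon \sim \mathcal N(0,1)$ per unit and step. The
$\sqrt{2/\alpha}$ factor is the discrete counterpart of
$\sqrt{2\tau\sigma_{rec}^2}$ for unit-variance per-step draws: halving
$dt$ doubles the per-step variance factor so the integrated noise
variance over a fixed wall-clock interval is invariant (tested by Monte
Carlo). Noise enters *inside* $f$, never added to $r$, so the update is a
convex combination of nonnegative quantities and activity can never go
negative. A 1.5 s delay is exactly 75 steps.

**Initialization.** $W_{rec}$ random orthogonal (QR of a Gaussian matrix
with the Haar sign convention; residual
$\|W^\top W - I\|_\infty < 10^{-6}$ enforced by test), $W_{in} \sim
\mathcal N(0, 1)/\sqrt{n_{in}}$, $W_{out}$ Glorot-uniform on
$\pm\sqrt{6/(N + n_{out})}$, $b = 0$ and trainable. Weights are
unconstrained in sign (no Dale's law). The initial state defaults to
$r_0 = 0$ (configurable). Whether the original simulations trained $b$
is not documented; we make it trainable from 0, which reduces to the
fixed-$b$ case when gradients leave it near 0.

## Tasks and their encoding

The registry ships six tasks: ODR (respond toward a remembered cue after
a delay), ODRD (same, with a to-be-ignored distractor mid-delay),
anti-ODR and anti-ODRD (respond 180° opposite), and two zero-delay
pro/anti controls. Canonical timing: 1 s fixation, 0.5 s cue, 1.5 or 3 s
delay, and a 0.5 s response epoch (the response duration is our choice;
it comfortably exceeds the network's rise time of a few $\tau$).
Variable-delay training draws each trial's delay uniformly from
$\{0, 0.1, \dots, 3.0\}$ s (31 values).

Inputs are one fixation channel (1 while fixation is required, 0 after
the go signal), a ring of 8 (or 360) direction-tuned channels, and a
one-hot rule block held on for the whole trial. The ring code is a
von-Mises bump, $a\,e^{\kappa(\cos\Delta - 1)}$, with $\kappa = 3.75$ so
that units 45° from the stimulus receive about one third of the peak
drive — a graded code that stays informative when the ring is refined to
360 units; $\kappa = \infty$ gives a one-hot code. All input channels
receive additive Gaussian noise, $\sigma_{in} = 0.01$ per step — the
magnitude is not documented for the original study; we chose a value
small relative to the signal (peak drive 1) and kept it fixed
throughout.

Targets: fixation output 1 while fixation is required and 0 afterwards;
ring targets are a bump of peak 1 on the required direction during the
response epoch over a 0.05 baseline. The loss mask up-weights the
response epoch fivefold and zeroes the first 100 ms after the go signal
(grace period) so the readout's finite rise time is not penalized; the
same grace applies nowhere else — the fixation-hold behavioral check
runs only while fixation is required.

## Training and staging

Training is supervised: masked mean-squared error
$L = \sum m (z - y)^2 / \sum m$ over stratified minibatches ($M = 64$;
all tasks interleaved in every batch), minimized with Adam
($\eta = 0.001$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) through full backpropagation through the unrolled
trial (no truncation; trials are at most ~250 steps). The MSE form is our
choice — the outputs are bounded logistic activations and the original
account specifies only "a cost function representing the difference from
the target". Gradients are clipped at global norm 1 (counted when
active); non-finite gradients skip the update and are counted.
$\sigma_{rec}$ stays at its training value during evaluation — the
network is inherently noisy, and so is its behavior.

Performance is estimated on fresh seeded trials with *cue locations
balanced round-robin* within each task. This stratification matters for
the stopping rule: threshold-stopped networks often retain one location
with a large systematic endpoint bias, and an evaluation with uniformly
random cues can miss that location entirely in a small trial set
(probability $(7/8)^n$), spuriously certifying the network as fully
trained. Training minibatches, in contrast, draw cues uniformly at
random. (The default of 24 evaluation trials per task divides exactly
over the 8 locations.)

Performance stages partition $[0, 100]$ with half-open bands: early
$[0, 35)$, mid-trained $[35, 65)$, mature $[65, 95)$, fully trained
$[95, 100]$. (The printed band edges overlap at 65%; we resolve the
ambiguity half-open and test the partition property.) Training stops at
the fully-trained criterion or after `max_steps` updates; the first
checkpoint observed in each stage is kept so mid-trained networks can be
analyzed after the fact.

## Behavioral readout

The saccadic endpoint of a trial is the population vector of the ring
outputs — $\mathrm{atan2}(\sum z_i \sin\theta_i, \sum z_i \cos\theta_i)$
— averaged over the final 200 ms of the response epoch (window averaging
is our choice over a single final timestep; it is robust to output
transients and configurable). A trial is correct iff the fixation output
stayed above 0.5 at every step while fixation was required AND the
endpoint lies within 36° of the required direction, *inclusive* at the
boundary ("within" read inclusively; the tests pin 36.0 correct, 37
error at 1° output resolution). Angles are degrees, counterclockwise,
wrapped to $(-180, 180]$ everywhere.

## Unit-level diagnostics

All analyses consume a recording of unit rates at every 20 ms bin plus
the scored behavior table, and are pure functions of their inputs.

**Delay units.** A unit generates persistent activity if its per-trial
mean delay-period rate significantly exceeds its fixation-period rate
(Welch two-sample t, $p < 0.05$, delay mean > fixation mean). Welch is
our choice wherever a two-sample test is unspecified; degenerate
zero-variance ties are never selected.

**Tuning and rotation.** Per-unit mean delay rates by cue location give
the preferred location (argmax); curves are re-indexed so the preferred
location sits at offset 0 (offsets wrapped to $(-180, 180]$, i.e.
$-135°, \dots, 180°$ on the 8-location grid). Rotation preserves the
sum over locations and puts the argmax at the center by construction
(both tested).

**Rate–behavior correlation.** For each delay unit and location, across
correct trials: rate deviation = last-1 s delay rate minus the
per-location median; saccade deviation = absolute deviation of the
endpoint from the per-location median endpoint, signed positive when the
endpoint moved *toward* the unit's preferred location. "Toward" is made
precise as reducing the circular distance to the preferred location
relative to the median endpoint; exact ties (possible at offsets 0 and
180) are excluded. Medians are taken on deviations-from-cue, which are
already wrapped. Pearson r per unit-location cell, a one-sample t-test
of the cells against 0, and a rotated, unit-averaged curve. If delay
activity drifts and the drift is read out, flank locations
(±45°…±135°) correlate positively while the center and opposite
locations do not — the "M" shape.

**Fano factor.** Per unit and location, the variance (n−1 denominator,
our convention) of per-trial delay-window mean rates across 16 correct
trials, divided by their mean. The window is a parameter: the original
description mentions both the entire delay and its last second; the
default is the last 1 s (matching the correlation analysis) and the
acceptance script logs both. Rate units are nearly deterministic, so
values are of order 10⁻², roughly two orders below the ≈1 of Poisson
spike counts — the package computes the Poisson reference through the
same `fano()` code path. A drifting bump makes this curve M-shaped too,
and a one-way ANOVA of Fano factor on rotated location (units as
observations) tests that structure.

**Correct vs error.** Per delay unit, trials at the unit's preferred
location are split by outcome, and the per-unit condition means are the
observations; several networks pool by row-binding observation tables.
Welch t, two-tailed. Direction (correct > error) is the claim; exact t
values are run-specific.

**Weight structure.** Recurrent dimensions sorted by preferred location;
the diagonality statistic is the mean recurrent weight between pairs
tuned within 45° minus the mean between pairs 135° or more apart
(circular, diagonal excluded). Like-to-like connectivity gives positive
values; the permutation null is centered on 0 (tested).

## The drifting-bump surrogate

`make_bump_surrogate()` generates a population recording with known
ground truth: a bump appears at the cue and performs a Gaussian random
walk (default 15°/√s); unit rates are von-Mises tuning evaluated at the
bump position plus small observation noise, and the endpoint *is* the
bump position at the go signal. It exists to validate the analysis code:
the M-shaped correlation and Fano curves must emerge when drift is on
and vanish when `drift_sd = 0`. It emulates none of the things that make
trained networks interesting — no dynamics, no heterogeneous tuning, no
cue/delay preference dissociation, no fixation behavior — so passing
surrogate tests certifies the statistics, not the biology. The trial
generator itself (`sample_batch()`) is the synthetic-data source for all
network-level tests.

## Problem sizes and numerical choices

The test suite and acceptance script run a desk-scale version of the
study: 128 recurrent units (half the typical 256), ODR only with a fixed
1.5 s delay, 24 trials per location for analyses (≥16 correct per
location at fully-trained performance), and 3-network ensembles for the
pooled statistics (the full-scale study pools ~30 networks; pooling is
by row-binding tables, so scale is a config knob, not a code path).
These sizes were chosen so a single training run converges in a few
hundred Adam updates and the full pipeline completes in minutes on one
core, while every qualitative result (attainment, M-shapes, correct >
error, diagonality) is already stable.

Other numerical choices: orthogonality tolerance $10^{-6}$;
divide-by-zero guards at $10^{-6}$ (baseline normalization, Fano means)
with excluded cells counted and reported, never silently dropped;
population-vector resultants below $10^{-9}$ flagged "no response";
checkpoint round-trips bit-exact; every forward pass a pure function of
(parameters, inputs, seed), with named substreams derived from the master
seed so adding analyses never perturbs training randomness.

## Known limitations

- Rate units with Gaussian state noise cannot reproduce spiking
  variability; Fano factors are two orders below cortical values by
  construction, and only their *structure* across locations is
  comparable.
- Magnitudes of the variability statistics scale with the configuration.
  In desk-scale 128-unit single-task networks the per-unit rate-behavior
  correlations are strong (pooled mean r of order 0.1–0.3 per run of the
  acceptance pipeline) — closer to the drifting-bump surrogate's
  ground-truth value (≈ 0.6) than to large multi-task ensembles, where
  each unit carries a smaller share of the behavior and pooling over many
  network instances dilutes the mean. Conversely the mean Fano factor is
  of order 0.003: the pinned noise sources (`sigma_rec = 0.05`,
  `sigma_in = 0.01`) are the only variability, so trial-to-trial
  repeatability is extreme. The *shapes* (M-curves, positive significant
  correlation, Fano far below Poisson) are the robust, configuration-
  independent findings.
- Threshold-stopped networks often retain one location with a systematic
  endpoint bias near the 36° criterion; errors therefore concentrate at
  one or two locations per network, which makes per-unit correct-vs-error
  contrasts data-starved at desk scale (the effect in the literature
  rests on pooling many network instances of heterogeneous quality).
- Fixed-delay training yields time-locked, often "ringing" dynamics;
  variable-delay training gives more stable persistent activity. The
  analyses accept either, but desk-scale defaults train fixed-delay
  networks because they converge fastest; variable-delay runs are a
  config switch (`delay_mode: variable`) and were exercised only in
  development, not in the shipped test suite, for runtime reasons.
- The anti-response mapping is handled throughout in "memory space"
  (endpoints mapped back through the 180° rule before bump analyses),
  but the published correlation/Fano analyses concern the pro task and
  that is what the acceptance pipeline runs.
- The exact composition of the original six-task battery lives in prior
  work; the shipped registry is a faithful functional substitute
  (pro/anti × delay/distractor/zero-delay), and the trained battery is
  configurable.
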