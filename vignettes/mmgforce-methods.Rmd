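---
title: "Estimating dynamic muscle force from multichannel MMG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic muscle force from multichannel MMG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmgforce)
```

## The problem

Mechanomyography (MMG) records the low-frequency mechanical vibration of a
contracting muscle on the skin surface, typically with an accelerometer. For
the knee extensors, three sensors over the rectus femoris (RF), vastus
lateralis (VL) and vastus medialis (VM) plus a force transducer give a
multichannel time series from which the dynamic extension force can be
regressed. Two obstacles dominate in practice:

* **Cross-talk** — each skin-surface sensor picks up vibration from
  neighbouring muscles, so a channel is a mixture of sources rather than a
  clean readout of "its" muscle.
* **Temporal structure** — force at time *t* depends on the recent history
  of muscle activity, so pointwise regressors underuse the signal.

`mmgforce` implements a complete pipeline around these two observations:
quantify cross-talk per muscle pair, prefer the channel with the least of
it, and regress force with a recurrent (LSTM) model whose hyper-parameters
are tuned by a population metaheuristic.

## Cross-talk quantification

For two channels $x$ (length $N$) and $y$ (length $M$), the lag-weighted
cross-correlation coefficient is

$$R(\tau) = \frac{\sum_n x(n)\,y(n+\tau)}{\sqrt{a\,b}\;\omega(\tau)},\qquad
a = \sum_n x(n)^2,\quad b = \sum_n y(n)^2,$$

with the triangular overlap weight
$\omega(\tau) = (\max(N,M)-|\tau|)/\max(N,M)$ removing the bias of the
shrinking overlap at non-zero lags. The **PCCC** (peak cross-correlation
coefficient) of a pair is $\max_\tau \min(|R(\tau)|, 1)$; values below 0.30
are read as essentially uncontaminated, 0.30–0.70 as moderate and above
0.70 as strong cross-talk. Note that a $\sqrt{a\,b}$ denominator is the
only normalization under which a signal correlated with itself at zero lag
scores exactly 1, which the interpretation scale presumes; a variant that
divides by $a\,b$ is available behind `normalization = "printed"` for
comparability with sources that print that form.

Numerical choices:

* The raw lag sums are computed by FFT (circular correlation on a padded
  grid); a direct-summation mode (`method = "direct"`) exists as a slow
  reference, and the two agree to $10^{-9}$.
* The default lag window is $\pm 0.5$ s. The $\omega$ correction makes
  extreme lags unstable (it divides by a vanishing overlap), and physical
  cross-talk peaks sit near zero lag; a `"full"` mode exists.
* The absolute value is used because accelerometer mounting polarity is
  arbitrary; coefficients are clipped at 1.
* Both band boundaries (0.30, 0.70) classify as `moderate`.
* On a 2 s band-limited segment the *spurious* PCCC floor between truly
  independent channels is roughly 0.2–0.3 (a few hundred effective samples,
  a thousand lags searched), so "low" findings on short segments should be
  read against that floor.

## Windowed features and screening

Each channel is band-passed (4th-order zero-phase Butterworth, 5–100 Hz by
default) to strip limb-motion drift and wide-band sensor noise; the force
channel is low-passed at 5 Hz (3rd order, zero phase). The first and last
10 s of a 60 s trial are discarded as unstable. A 250-sample window
(250 ms at 1000 Hz) slides in 50-sample hops, and 25 descriptors are
extracted per window and channel, spanning four families:

* time domain (8): MAV, RMS, variance, SD, waveform length, zero
  crossings, slope-sign changes, integrated absolute value;
* frequency domain (7), from a linearly detrended periodogram: mean,
  median and peak frequency, total and mean power, spectral moment ratio
  $M_2/M_1$, frequency SD;
* time–frequency (5): relative energies of the four db4 detail levels and
  the wavelet entropy over all five subbands;
* nonlinear (5): sample entropy and approximate entropy ($m = 2$,
  $r = 0.2\,\mathrm{SD}$), Higuchi fractal dimension ($k_{max} = 8$),
  Lempel–Ziv complexity after median binarization, and the detrended
  fluctuation exponent.

This bank is a documented default, chosen to span the four families with
standard members; it is not claimed to match any particular previously
published 25-item list, and it is swappable. Two members (IAV and mean
power) are exact positive multiples of others (MAV, total power) at fixed
window length; they are retained for completeness of the conventional
families but carry no independent information here.

Each window is paired with the mean force over the window (the 5 Hz-filtered
force is nearly constant within 250 ms; `last` and `center` rules exist).
Features are then screened by **grey relational analysis**: after min–max
normalization, the grade of feature $x_i$ against the force target $x_0$ is
the mean over time of
$\xi_i(k) = (\Delta_{min} + \rho\Delta_{max})/(\Delta_i(k) + \rho\Delta_{max})$
with $\rho = 0.5$ and $\Delta$ the absolute deviation; $\Delta_{min/max}$
are pooled over the batch (classical Deng formulation; a per-feature mode
gives batch-independent grades). The top 10 features by grade are kept by
default — the count is a design default, not an estimate; a grade-threshold
rule is available. Screening and the Z-score statistics (population SD)
are computed on the chronological training partition only and frozen before
touching test rows.

## Models

The regressor is a single-layer **LSTM**: input layer, one recurrent hidden
layer with the standard three-gate cell, a fully connected layer and a
scalar regression output. Training is full-sequence backpropagation through
time with Adam on the RMSE loss, global-norm gradient clipping at 1, and
uniform $\pm 0.08$ initialization from a seed — training is exactly
reproducible. Fixed-configuration fits use 100 hidden units, learning rate
0.005 and 250 epochs. At prediction time the recurrent state is carried
over from the end of training, which is correct for the chronological test
partition used throughout (the last 10% of windows). Baselines: a
one-hidden-layer back-propagation network trained by full-batch gradient
descent on the MSE, and an RBF-kernel $\varepsilon$-SVR.

Estimates are scored with $\mathrm{NRMSE} = \mathrm{RMSE}/(y_{max}-y_{min})$,
$\mathrm{MAPE} = \frac1N\sum|\hat y_i - y_i|/|y_i|$ reported as a fraction
(not a percentage), and the Pearson correlation $R$. Force targets are
fractions of maximum force in the 0.2–0.6 range, so the MAPE denominator is
never near zero on realistic data; the generator additionally floors force
at 0.05.

## Hyper-parameter search

The **grey wolf optimizer** (GWO) minimizes a fitness over a box by moving
a pack of candidate positions toward its three best members
($\alpha,\beta,\delta$); the exploration amplitude $a(t)$ shrinks from 2 to
0 over iterations. The **improved** variant adds three independently
toggleable changes aimed at the canonical algorithm's slow start and
late-stage stagnation: tent-map chaotic initialization, a cosine
convergence factor $a(t) = 2\cos(\pi t / 2T)$ that keeps exploration high
for longer, and greedy per-wolf selection (a move that worsens a wolf's
fitness is rejected, making each wolf's fitness non-increasing). With all
flags off the implementation reduces bit-for-bit to canonical GWO at the
same seed. This exact combination of improvements is this package's own
reconstruction of "improved GWO"; other variants exist in the literature.

For the LSTM the search box is hidden units in $[50, 400]$ (integer,
rounded only at evaluation) and learning rate in $[0.001, 0.01]$; the pack
has 10 wolves and runs 20 iterations. Fitness is the RMSE of an LSTM
trained at the candidate configuration. Two fitness modes exist: training
RMSE (the literal reading of "training output as fitness") and — the
recommended and pipeline-default mode — RMSE on the last 20% of the
training rows, which removes the incentive to simply maximize capacity.
Each evaluation trains from the same initialization seed so candidates are
compared fairly, and a diverged training is penalized with $+\infty$. The
final model is retrained at the tuned configuration for up to 300 epochs.

## The synthetic generator

No public multichannel MMG+force corpus matches this recording protocol,
so the package ships a generator whose *structure is the ground truth the
pipeline is supposed to recover*. It is an explicit invention — a
statistical emulator, not a physiological simulation:

* Each muscle has an activation envelope $a_m(t)$: a common drive (0.1 Hz
  sinusoid sweeping 20–60% of maximum by default, emulating a 1-min
  dynamic contraction; ramp and plateau-staircase profiles exist for
  static-protocol fixtures) blended with muscle-specific slow wander
  (low-passed noise, 0.25 Hz cutoff). The default wander fraction is 0.8:
  muscles share a modest common drive but mostly fluctuate independently,
  which is what makes "which muscle drives force" identifiable at all.
* Latent sources are unit-RMS Gaussian noise band-limited to 5–45 Hz,
  amplitude-modulated by $a_m(t)$; channel $i$ observes
  $\sum_m \mathrm{mixing}_{i,m}\, s_m(t)$ plus white sensor noise. The
  default mixing gives the RF-analog channel heavy contamination from both
  vastus analogs, the VM-analog moderate contamination, and the VL-analog
  the least — so the adjacent pairs (RF–VL, RF–VM) show more cross-talk
  than the non-adjacent pair (VL–VM), reproducing the anatomically
  expected ordering.
* Force is the 2 Hz-low-passed weighted sum of the activation envelopes
  plus measurement noise. The default weights put all weight on the
  VL-analog, so the cleanest channel is also the one whose activation the
  force follows: the "best single muscle" question has a known answer.
* All randomness derives from one seed through a counter-based sub-seeding
  scheme; a configuration reproduces its recording bit for bit.

What the generator does **not** emulate: fatigue and slow non-stationarity,
motor-unit discreteness, activation-dependent spectral shifts, sensor
artifacts beyond white noise, and inter-subject variability. Consequently,
passing recovery tests here shows the pipeline recovers *this* structure;
it does not certify accuracy on real recordings.

## Experiments and problem sizes

Two experiment drivers mirror the standard study design. The
feature-combination comparison trains the fixed LSTM on each of F1–F7
(F1 = RF, F2 = VL, F3 = VM, F4–F6 the pairs, F7 all three), each screened
and standardized on its own training rows, and evaluates on the last 10% of
windows. On the default generator the VL-only combination F2 attains the
lowest mean NRMSE — by construction of the force law, the right answer.
The model comparison trains BPNN, IGWO-SVR, fixed LSTM and IGWO-LSTM on
identical data (same split, same GRA mask, same scaler — asserted, not
assumed) and recovers the expected ordering: the tuned LSTM is at least as
good as the fixed one on average, and both recurrent models beat the
pointwise baselines, whose window-local view cannot average out the
envelope-estimation noise.

The package's own test and acceptance runs use one 60 s trial per seed at
1000 Hz (40 s after trimming), a 50-sample hop for the combination
experiment (796 windows) and a 250-sample hop with 6-epoch tuning fitness
for the model comparison; these sizes are the package's choices for
routine, single-machine verification, and all of them are parameters.
Stochastic recovery claims are asserted on seed-ensemble means, never on
individual seeds.

## Known limitations

* The 25-feature bank and the IGWO variant are documented defaults, not
  reconstructions of any specific prior list.
* Greedy per-wolf selection interacts with the shrinking search amplitude;
  on deceptive fitness landscapes the canonical update can occasionally
  win. The variant flags exist precisely so this can be measured.
* The LSTM trains full-batch on one sequence; mini-batching across trials
  is out of scope.
* MAPE is undefined at zero force; callers feeding absolute (not
  fraction-of-maximum) forces should rescale first.
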