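---
title: "Modelling serotonin voltammetry in a Parkinsonism mouse model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serotonin voltammetry in a Parkinsonism mouse model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

serovolt re-implements, on fully synthetic data, the computational chain of a
study of hippocampal serotonin in MPTP-parkinsonian mice: fast-scan cyclic
voltammetry (FSCV) color plots and their evoked traces, ambient serotonin by
fast-scan controlled-adsorption voltammetry (FSCAV), two-uptake
Michaelis–Menten reuptake kinetics, a convolutional network that reads the
serotonin:dopamine composition of a color plot, and a reduced ordinary
differential equation model of the serotonergic and dopaminergic projections
to the hippocampus. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic experiments can and
cannot say about real recordings.

## Synthetic FSCV data

An FSCV **color plot** is a current matrix: rows are samples of the applied
potential within one sweep of the serotonin waveform (0.2 V to 1.0 V to
−0.1 V to 0.2 V at 1000 V/s, so one sweep covers 2.2 V of path in 2.2 ms and
yields 220 samples at 100 kHz), and columns are successive sweeps applied at
10 Hz. The generator composes a plot as

$$I_{ij} = T_i \cdot C(t_j)/49.5 + d\, t_j + \varepsilon_{ij},$$

an outer product of a unit-amplitude cyclic-voltammogram template $T$ and an
evoked concentration transient $C(t)$ (nM, converted to current through the
49.5 nM/nA electrode calibration factor), plus a linear drift $d$ and white
noise $\varepsilon$. Templates are Gaussian oxidation bumps on the anodic
segment and reduction troughs on the cathodic segment. The serotonin
oxidation centre is 0.65 V — inside the 0.4–0.8 V window used for FSCAV
charge integration — and the dopamine centre is placed at 0.45 V. The
direction of the dopamine shift is a design choice (the oxidation potentials
of the two analytes overlap heavily; only the *existence* of a shift is
anchored), and both centres are configurable. Drift is modelled as linear in
time; it exists precisely so that averaging repetitions is meaningful, which
is the practice the kinetics fitter mirrors.

The **source cohort** mimics the study's data volume: 28 serotonin plots
(7 animals × 4 repetitions) and 21 striatal dopamine plots (3 animals × 7
repetitions), with per-animal jitter on template position/width and kinetic
gains, and per-repetition amplitude jitter, drift and noise. Serotonin
transients are integrated from the two-uptake model below with the saline
group parameters; dopamine transients use fast, high-capacity uptake typical
of the striatum (Vmax 3500 nM/s, Km 200 nM, release 2000 nM/s), giving the
sub-second clearance that distinguishes striatal dopamine.

A note on amplitudes: integrating the two-uptake model with the printed group
parameters (with both mechanism weights at 1) yields evoked amplitudes of
about 4–7 nM, well below the printed group-mean amplitudes (~28–40 nM). The
dominant second uptake term (780 nM/s, Km 170 nM) clears serotonin too fast
for larger peaks. The generator keeps the printed parameter set — internal
consistency of the round trip matters more here than absolute amplitude — but
real recordings presumably reflect different effective weights. This is the
main known gap between the synthetic and the real signal scale.

The plot container round-trips through a CSV matrix plus JSON sidecar, with
currents serialised at full precision (`%.17g`) so that a plot read back from
disk predicts bit-identically.

## Mixture augmentation

Training data for the ratio network are convex mixtures
$X_k = r_k A + (1 - r_k) B$ of one standardized serotonin plot $A$ and one
standardized dopamine plot $B$, with $r_k \sim U(0,1)$ (uniform chosen as the
least-informative reading of "randomized ratio from 0 to 1"). Standardization
(zero mean, unit SD) precedes mixing so amplitude differences between
acquisitions cannot leak into the label; mixtures are deliberately **not**
re-standardized, which preserves the exact endpoint identities
$X(1) = A$, $X(0) = B$ and keeps the mean at zero by linearity. The default
volume is 5000 mixtures per serotonin animal. Gaussian input noise
(SD 0.05 in standardized units) is drawn fresh for every training batch
rather than baked into the set, so each presented signal is unique while the
dataset itself stays a pure function of its seed.

## The ratio CNN

The regressor is an 11-layer sequential network: convolution (275 features,
3×3) with SELU activation, max pooling (3×3), leaky ReLU, convolution
(100 features, 3×3, ReLU), leaky ReLU, flatten, then dense layers (128 and
64 units by default, widths not anchored) interleaved with leaky ReLUs and a
unity output node — 2 convolutions + 1 pool + 4 leaky ReLUs + 1 flatten +
3 dense = 11. The printed SELU form, $s(\alpha e^x - 1)$ for $x \le 0$ with
$s = 1.051$, $\alpha = 1.673$, is discontinuous at the origin (value ≈ 0.707
approaching from below); the package implements the standard continuous form
$s\,\alpha\,(e^x - 1)$ by default and keeps the printed variant behind
`selu_printed_form = TRUE`. The leaky ReLU slope is 0.1. The exact placement
of the four leaky ReLU layers among the eleven is ambiguous in the source
description; the order above is the one implemented, and the count is what
the configuration validates.

Training uses Adam (learning rate 1e-4), mean absolute error, batches of 30
shuffled plots, a 4:1 train:test split and a 4:1 train:validation split, with
4 training steps and 5 validation steps per epoch and 500 epochs at full
scale. Forward and backward passes are implemented in the package (im2col
convolutions via BLAS matrix products, compiled gather/scatter and
element-wise kernels); everything stochastic — initialisation, splits, batch
shuffles, input noise — consumes one seeded generator, so training is
bit-reproducible on a single thread. Predictions are not clipped to [0, 1].

**Profiles.** The full-scale configuration (220×300 plots, 5000 mixtures per
animal, 275/100 features, 500 epochs) is faithful but not a desk-sized
computation. The shipped `test` profile scales every axis of the problem:
64×100 plots, 1000 mixtures, 16/8 convolution features with 32/16 dense
units, 100 epochs under the same 4-step/5-validation-step caps (~3 min on one
CPU). Width scaling is part of the profile because the 275-feature first
layer dominates cost without changing the character of the task. At this
scale the seeded run reaches held-out RMSE ≈ 0.015, pure-plot endpoint means
of ≈ 0.99 (serotonin) and ≈ 0.02 (dopamine), monotone bin means, and
recovers an emulated post-levodopa ratio ramp (1 → 0.6 over 120 min) with a
slope within a few percent of the generating ramp. Passing at this scale
shows the pipeline is correct and well-calibrated on data the generator can
produce; it does not certify performance on real recordings, whose
backgrounds, drift structure and inter-animal variability are richer than the
generator's.

**Feature importance** retrains the network (15 repetitions by default),
replaces each input block with fresh $U(-1,1)$ noise across an evaluation
set, and records the ratio of perturbed to baseline RMSE, averaged and
normalised to a maximum of 1. Blockwise evaluation (default 4×4 pixels) keeps
the cost at full resolution tractable; `block = c(1, 1)` is the per-sample
variant. Structurally empty regions leave the error essentially unchanged
(raw ratio ≈ 1); oxidation-peak rows dominate the map.

## Evoked-trace metrics and reuptake kinetics

Traces are the color-plot row nearest the oxidation potential (ties to the
lower index), converted by 49.5 nM/nA. `peak_amplitude()` subtracts a
pre-stimulation baseline (mean of the second before onset; zero when the
trace starts at onset) and searches 15 s past onset. `auc_simpson()` is
composite Simpson with a trapezoid fallback on the last interval when the
interval count is odd. `half_life()` fits $c_{peak} e^{-kt}$ by log-linear
least squares to post-peak samples above 5% of the peak (a floor that keeps
tail noise out of the fit) and returns $\ln 2 / k$, rejecting non-decaying
segments.

The kinetic model is

$$\frac{dC}{dt} = R(t)\,(1 - A(t)) - \alpha \frac{V_{max1} C}{K_{m1} + C}
  - \beta \frac{V_{max2} C}{K_{m2} + C},$$

with uptake 1 the SERTs and uptake 2 the low-affinity transporters.
$R(t)$ is a rectangular pulse of height $R_{max}$ over the 2 s stimulation
(only maximum release rates are anchored); $A(t)$, the autoreceptor
occupancy, defaults to zero — no functional form is anchored — with an
optional first-order occupancy model available; $\alpha = \beta = 1$ (the
fitted $V_{max}$ values absorb the weights). The forward simulation uses
`deSolve::lsoda` at rtol 1e-8, split at the stimulation edges.

`fit_mm()` minimises the sum of squared residuals with free parameters
$\{V_{max1}, K_{m1}, R_{max}\}$ and the second mechanism fixed, the
rationale being that the number of uptake-2 transporters does not change.
Gradients are exact: forward sensitivity equations are integrated alongside
the state by a compiled fixed-step RK4 (sub-step 20 ms by default, release
indicator held constant per sub-step so the pulse edges are handled exactly
on aligned grids; a test pins this integrator to the adaptive solver). The
descent operates on log-parameters — positivity for free and better scale
balance — using Barzilai–Borwein spectral step lengths under a monotone
backtracking safeguard, stopping at a 1e-6 gradient norm or 10,000
iterations. On noiseless self-generated traces this recovers the free
parameters to ~1e-4 relative error in a few hundred iterations; an
independent Levenberg–Marquardt fit (minpack.lm) agrees in the test suite.
Fits target the group-average trace, matching the stated practice that
averaging removes the noise and drift that make single-trace fits unstable.

## FSCAV: charge, calibration, dosing epochs

Ambient serotonin is quantified by integrating the baseline-subtracted CV
current over the 0.4–0.8 V anodic window (the baseline is the chord across
the window edges; nA·s are reported as pC), then mapping charge to
concentration through an ordinary-least-squares post-calibration over
standards at 10, 25, 50 and 100 nM. The synthetic FSCAV series is
piecewise-linear in its means — 30 min control, 30 min after saline, 60 min
after escitalopram with slopes of 0.39 (control) and 0.21 nM/min (MPTP) on
baselines of 32.65 and 11.46 nM — plus Gaussian minute-to-minute noise. The
noise SD defaults to 2 nM: only SEMs of group means are anchored (±1.88 nM
over five animals), so a single-electrode SD of this order was chosen once as
realistic. `escit_effect_summary()` reports after-minus-before differences
of group means and per-epoch least-squares slopes; significance testing is
out of scope and left to standard routines.

## The reduced monoamine projection model

The full published base model of the serotonin–dopamine system lives in a
prior publication; this package implements a reduced structure that carries
exactly the mechanisms the present experiments probe. Eight states, rates per
hour, concentrations in nM (the DRN value is reported in µM where the
stimulation function expects it):

* **DRN serotonin** $c$: release proportional to the firing drive
  $\phi = f\,(1.5 - c^2/(0.000968^2 + c^2))$ ($c$ in µM), saturable uptake
  with $K_m$ set at the healthy equilibrium 0.000968 µM and $V_{max}$ twice
  the release gain, so that $\phi = 1$ exactly at equilibrium when all SNc
  cells are alive ($f = 1$). All DRN drive is attributed to the SNc per the
  stated assumption; a `non_snc_drive` fraction (default 0) implements the
  caveat that independent drive would flatten the degeneration slope.
* **Hippocampal serotonin** $s$: release $g\,\phi\,v_5$ from a vesicular
  pool, SERT uptake $V_S (F/(F+B))\, s/(K_S + s)$ with $K_S$ = 170 nM scaled
  by the free-transporter fraction, and first-order diffusion loss
  (0.5 h⁻¹).
* **Vesicular pools** $v_5$, $v_{DA}$: constant synthesis (serotonin) or
  AADC conversion of cytosolic levodopa (dopamine), leakage at 40 h⁻¹ — the
  anchored value that brings ambient serotonin down to 35 nM — and
  firing-gated release at 2 h⁻¹. Leakage dominating release is what makes
  the hippocampal serotonin equilibrium respond almost linearly to the
  drive.
* **Hippocampal dopamine** $d$: release proportional to $f$, DAT uptake with
  capacity proportional to $f$ (transporter density tracks surviving
  terminals), constant diffusion loss (1 h⁻¹). This ratio structure is what
  produces dopamine homeostasis: release and uptake shrink together, so the
  equilibrium barely moves until diffusion — the $f$-independent term —
  takes over at very low survival.
* **Levodopa pathway**: a single-exponential absorption into serotonergic
  terminals (2 h⁻¹), first-order AADC conversion (2 h⁻¹) into $v_{DA}$,
  co-release with serotonin in proportion to $\phi$, clearance by the
  $f$-scaled DAT plus diffusion. Pulse amplitude is therefore non-monotone
  in $f$: moderate degeneration removes DATs (bigger pulses), severe
  degeneration removes the drive (smaller pulses).
* **Escitalopram** $E, F, B$: $dE/dt = I(t) - 0.371 E$ with a
  single-exponential input $I(t) = I_0 e^{-2(t - t_{dose})}$, and mass-action
  SERT binding $k_1 = 7$, $k_2 = 20$. The bound state is integrated and
  $F$ reconstructed as total minus bound, so $F + B$ is conserved exactly by
  construction (and the derivative identity $dF + dB = 0$ is tested). Units
  of 0.371, $k_1$, $k_2$ are not stated at the source; hours are assumed,
  consistently with the 40 h⁻¹ leakage.

**Calibration** (`calibrate_monoamine()`) solves the free gains from the
anchors rather than tuning them: vesicular synthesis from the 35 nM
serotonin target, dopamine release from a 5 nM ambient dopamine target
(a typical hippocampal scale; only relative dopamine is anchored), and the
drug input amplitude $I_0$ by scalar root-finding so the simulated peak
occupancy $\max_t B/(F+B)$ equals 50%. Remaining constants (SERT
$V_{max}$ = 1000 nM/h, $K_S$ = 170 nM, diffusion rates, DAT
$V_{max}$ = 4000 nM/h, $K_D$ = 200 nM, release constants) were fixed once so
that the calibrated model also satisfies the anchored orderings — dopamine
homeostasis until >80% cell loss, near-linear serotonin decline, and the
levodopa pulse ordering across $f$ — and are documented defaults, not fitted
quantities.

**Numerics.** Trajectories use `lsoda` (rtol 1e-8, atol 1e-12), split at dose
times. Equilibria integrate in 200 h chunks with a Newton polish on the
algebraic fixed point (numerical Jacobian), declaring convergence at a scaled
derivative norm of 1e-10; integration alone cannot reliably reach that floor,
the polish makes the equilibria solver-independent. Degeneration sweeps warm
start each survival fraction from the previous equilibrium. States are
clamped non-negative inside the right-hand side and verified non-negative in
tests.

**Limitations.** The model omits the full species inventory of the published
base model (autoreceptors, synthesis regulation, the striatal circuit); DRN
SERTs are not blocked by escitalopram (only hippocampal uptake is), which
slightly understates the DRN feedback; absolute dopamine pulse sizes are not
meaningful (the anchored absolute values are dimensionally doubtful at the
source), only their ordering in $f$ is; and the escitalopram input shape is a
parametric stand-in for a published blood–brain-barrier profile, constrained
only by its elimination constant and the 50% occupancy target.

## Problem sizes and determinism

The test suite and the acceptance script run entirely at the reduced scale:
64×100 plots, 1000 mixtures, 100-epoch CNN training (~3 min), kinetics fits
at 10 Hz over 30 s (sub-second each), and ODE experiments over minutes of
CPU time; the full-scale profile is available but is a long computation. All
generators and the trainer are pure functions of (parameters, seed); every
derived seed stays within the 32-bit range.
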