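---
title: "Hybrid spatio-temporal networks: model, learning rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid spatio-temporal networks: model, learning rules and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnet)
```

## Overview

`stnet` implements two hybrid classifiers that couple a conventional
sigmoid network (an ANN, carrying a continuous *spatial* code) to a
spike-response-model network (an SNN, carrying a *temporal* code in firing
times), trained jointly: ordinary gradient descent through the sigmoid
units, SpikeProp-style temporal backpropagation through the spiking units.
This vignette is the package's account of the model, the learning rules,
and every numerical decision that was genuinely open — what we chose,
and why.

## Neuron models

**Sigmoid unit.** `R_q = f(Σ_n w_nq x_n)` with the logistic `f`; a
constant bias input of value 1 is appended to every feature vector
(`add_bias()`). One sigmoid hidden layer is used throughout: together with
the non-trainable coding layer the networks are "pseudo-four-layer", i.e.
computationally three-layer.

**Spike-response neuron.** Each connection carries `K` synapses with
distinct delays `d_k = k` time units. An input spike at `t_q` contributes
through synapse `k` a postsynaptic potential `v_qj^k · ε(t − t_q − d_k)`
with the alpha-shaped kernel

$$\varepsilon(s) = \frac{s}{\tau}\,e^{1-s/\tau}\;(s>0),\qquad
\varepsilon(s)=0\;(s\le 0),$$

which rises from zero, peaks at exactly 1 when `s = τ`, and decays. The
membrane potential is the sum of all weighted PSPs; the neuron fires once,
at the first time `u_j(t) ≥ θ`, or stays silent if the threshold is never
reached within the window `[0, T]`. A silent neuron's downstream spike
time is clamped to `T` (with a `fired = FALSE` flag kept for diagnostics),
which makes the forward pass total: every layer always emits a full
spike-time vector.

## Coding layers

The coding stage holds no trainable parameters — it only converts between
domains:

* **Reciprocal coding** (`reciprocal_encode()`): `t_q = β / R_q`, so
  stronger spatial features spike earlier; `t_q > T` is forcibly set to
  `T` and flagged. The clamp is flat, so no gradient flows through clamped
  entries.
* **Linear time-delay coding** (`linear_delay_encode()`):
  `t = (x_max − x)/(x_max − x_min) · T` — the low-cost encoder for
  high-dimensional inputs.
* **Gaussian population coding** (`population_encode()`): each feature is
  represented by `G` overlapping Gaussian receptive fields. The field
  layout is the classical temporal-coding scheme: for a feature on
  `[lo, hi]`, centers `lo + (2g−3)/2 · (hi−lo)/(G−2)` and common width
  `(hi−lo)/(γ(G−2))` with `γ = 1.5`. The activation-to-time map is our
  choice: `t = T(1 − φ)`, so a field centered on the value fires at 0 and
  distant fields fire near `T`. All constants are configurable in
  `coding_config()`.
* **Label coding** (`encode_labels()`): the true class's output neuron is
  expected at `t_early = 3`, all others at `t_late = T`. These target
  times are not fixed by the model family; we chose `t_early` far enough
  inside the window that the correct neuron must fire decisively early,
  and `t_late` at the window end so "wrong" neurons may equivalently fire
  late or stay silent. Decoding is by earliest output spike.

The parallel network switches its SNN path to linear coding automatically
once `N·G > 256` input neurons would be needed (`encoding = "auto"`),
mirroring the practice of dropping population coding for many-feature
data; the threshold is an explicit, overridable default.

## Learning rules

With expected times `t^d` and actual times `t`, the per-sample loss is
`E = ½ Σ_j (t_j − t_j^d)²`. SpikeProp differentiates the firing time
through the threshold crossing: `∂t_j/∂u_j = −1/(∂u_j/∂t)(t_j)`. The
resulting per-sample updates, all applied online:

* output SRM weights: `Δv_qj^k = −η δ_j ε(t_j − t_q − d_k)` with
  `δ_j = (t_j^d − t_j) / Σ_{q,k} v_qj^k ε'(t_j − t_q − d_k)`;
* sigmoid weights (through the reciprocal coding):
  `Δw_nq = η β (∂E/∂t_q) R_q(1−R_q) x_n / R_q²`, where
  `∂E/∂t_q = Σ_j δ_j Σ_k v_qj^k (−ε'(t_j − t_q − d_k))`; columns whose
  coding time was clamped receive no update;
* parallel upper-path SRM weights: the hidden SpikeProp rule
  `Δb_mp^k = η (∂E/∂t_p) ε(t_p − s_m − d_k) / Σ_{m,k} b_mp^k ε'(t_p − s_m − d_k)`,
  skipped (with a diagnostic count) for hidden neurons that did not fire.

Training stops when `epoch ≥ max_epoch` or the epoch MSE (mean summed
squared time error per sample) drops to `min_mse`. The learning rate may
decay geometrically per epoch (`learning_config(decay = )`); with
`decay = 1` it is fixed. Presentation order is reshuffled each epoch with
a seedable RNG; this can be switched off for strict in-order replication.

Every analytic update is audited against an independent central
finite-difference oracle (`fd_loss_gradient()`), which perturbs one weight
coordinate by `±h` and re-simulates the whole network on each side — see
`analytic_loss_gradient()` for the per-coordinate reliability masks that
exclude coordinates sitting on loss-surface discontinuities (floored
denominators, coding clamps, silent neurons).

## Numerical choices

**Time grid and crossing refinement.** Layers are simulated on a uniform
grid `t = 0, dt, …, T` with `dt = 0.01` by default. The threshold crossing
is detected on the grid and then refined by linear interpolation inside
the crossing cell (`sim_config(refine = "linear")`). The refinement
matters: reported firing times then vary continuously with the weights,
which is exactly the relation SpikeProp differentiates — with raw grid
times the loss is a staircase and finite differences of it are
uninformative at any `h` below `dt`. `refine = "none"` reports the first
grid point at or above threshold for callers who want the plain grid
semantics.

**Denominator guards.** The SpikeProp denominator `∂u/∂t(t_j)` can be
arbitrarily small at shallow crossings; its magnitude is floored at
`denom_floor = 0.1` with the sign kept. For *silent* neurons the clamped
time `T` may sit on a decaying stretch of the potential where the raw
slope is negative; using it would push weights *down*, making the neuron
permanently unrecoverable. For unfired neurons the denominator is
therefore forced positive, keeping the update direction "raise the weights
until it fires".

**Step clipping.** A floored delta (`|δ|` up to `(t_late − t_early)/denom_floor`)
multiplied by the reciprocal-coding backward factor can produce a single
online update orders of magnitude larger than usual; such a jump saturates
the sigmoid layer, clamps the entire coding layer to `T`, and — because
the clamp passes no gradient — freezes training irreversibly. Every
per-sample weight increment is therefore clipped elementwise to
`±max_step` (default 0.2, far above ordinary update sizes). The backward
factor `β/R²` additionally floors `R` at `r_floor = 1e-3`.

**Initialization.** SRM weights are drawn uniformly on
`(0, 2θ/(K · n_pre · ε̄))` with `ε̄` the mean kernel value over the window,
targeting initial peak potentials that straddle θ; sigmoid weights use the
Glorot-style uniform range. Because SpikeProp learns nothing from a neuron
that never fires (and hidden upper-path neurons receive no update at all
while silent), `train_stnet()` additionally runs a *firing calibration*
before the first epoch: any spiking neuron silent on more than half of a
50-sample probe has its incoming weights scaled by 1.5, repeatedly (at
most 20 rounds). This matters mainly for population-coded inputs, whose
spikes are spread across the window so that the nominal presynaptic count
overstates the drive the neuron actually receives.

**Prediction edge cases.** The predicted class is the earliest-firing
output neuron. An exact tie is broken by the larger peak membrane
potential; if no output neuron fires, the neuron with the largest peak
over the window wins; remaining ties go to the lowest index. This keeps
prediction total and deterministic.

**Degenerate inputs.** Constant features normalize to 0 (with a warning)
and encode to `t = T` under linear coding; fully missing features are an
error for mean imputation; ragged or non-numeric delimited files fail
naming the offending row.

## The synthetic-data generator

`make_synthetic()` provides the study conditions for everything that must
run without external downloads:

* `blobs` — isotropic Gaussian clusters (unit standard deviation by
  default) at uniformly drawn centers in `[0, 10]^N`, redrawn until all
  pairwise center distances are at least 4: moderately separated classes,
  solvable but not trivial at 150 samples;
* `xor` — the 2-feature checkerboard, a linearly non-separable baseline;
* `rings` — concentric annuli, a radially non-separable baseline.

The generator is deterministic per seed and restores the caller's RNG
state. What it emulates is the geometry of small tabular benchmarks:
continuous bounded features, balanced classes, moderate class overlap.
What it does **not** emulate: feature correlations and heterogeneous
scales, label noise, missing values, class imbalance, and the
high-dimensional structure of image data. Tests passing on these fixtures
therefore demonstrate that the architectures, coding layers and learning
rules work as specified — not that the accuracies printed for real UCI or
image benchmarks are reproduced; those require the original datasets.

## Problem sizes used in the checks

The test and acceptance runs use sizes chosen to exercise every code path
at desk scale: gradient audits on 20 networks per architecture
(3–4 features, 3–4 hidden units, 2 classes, `K = 3`) at `dt = 1e-3` with
`h = 1e-4`; learning runs on 3-class, 4-feature blob datasets with 50
samples per class, 5-fold cross-validation, 60 epochs, 5 independent
seeds. Sixty epochs sits inside the 40–70 epoch range where the
small-benchmark runs of this model family typically stop, with headroom
against the conventional 100-epoch cap.

## Known limitations

* One spike per neuron; no refractoriness or multi-spike decoding.
* The grid simulator is O(`n_pre · K · n_post · T/dt`) per layer pass;
  very fine grids or very wide layers are costly.
* Online (per-sample) updates only — no minibatching, momentum or
  adaptive optimizers, matching the model family's plain gradient-descent
  formulation.
* The reciprocal-coding clamp and the silent-neuron rule both create flat
  regions: neurons parked there rely on the calibration/guard heuristics
  described above rather than on gradient signal.
* Training is stochastic in initialization and presentation order; the
  cross-validation utilities report means and standard deviations over
  repeats for this reason.
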