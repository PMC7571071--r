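---
title: "Gap filling for diurnal stem-moisture series: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap filling for diurnal stem-moisture series: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Capacitance sensors record plant stem moisture (volumetric water
content, %) at a fixed cadence — typically every 10 minutes, 144
samples per day.  Logger, power or communication failures leave *long
contiguous gaps*: hundreds of consecutive samples, longer than a full
diurnal cycle.  Short scattered holes are well served by interpolation;
a gap longer than roughly 100 samples spans real diurnal structure that
an interpolant cannot invent, and classical fills degrade quickly with
gap length.

`stemfill` implements a recurrent-network approach to this problem:

1. **Recursive window-push filling.**  A one-step forecaster (stacked
   LSTM, window length 200) is trained on the observed flank of the
   gap.  The window of the 200 values immediately before the gap
   predicts the first missing value; that prediction is appended, the
   oldest value dropped, and the window pushed forward until the gap is
   covered.  Because predictions progressively replace observations in
   the window, error *accumulates* along the gap.
2. **Bidirectional fusion.**  The same procedure runs backward from the
   post-gap flank on the time-reversed series.  The forward fill is
   most accurate near the gap's start, the reverse fill near its end,
   so the two are fused per index, `z_i = a_i x_i + b_i y_i` with
   `a_i + b_i = 1`: equal weights (`a = b = 0.5`), a decreasing
   staircase (`a`: 1.00 down to 0.05 in steps of 0.05, `b`
   complementary), or a hard segmented split (forward for the first
   half, reverse for the second).
3. **Covariate filling.**  When the gap is too long even for
   bidirectional recursion, aligned micro-environment channels — air
   humidity (AH), photosynthetically active radiation (PAR), soil
   temperature (ST) — drive a separate model that maps a covariate
   window to the concurrent stem-moisture value.  Each gap index is
   predicted independently from covariates, so there is no recursion,
   no feedback and no length limit.

## The recurrent cell and its parameter accounting

The LSTM cell uses the standard three-gate structure: a forget gate
`f_t = σ(W_f·[h_{t−1}, x_t] + b_f)` controlling retention of the cell
state, an input gate `i_t` admitting the candidate update
`tanh(W_c·[h_{t−1}, x_t] + b_c)`, and an output gate `o_t` exposing
`tanh(c_t)` as the hidden state `h_t = o_t ∘ tanh(c_t)`.  With input
width `n` and `m` units, each gate block holds `(n + m)·m + m`
parameters (fused-bias convention: one bias vector per gate), so a full
LSTM layer holds

    Param_LSTM = 4 · ((n + m) · m + m)

and a simple-RNN layer, having a single such block, exactly one quarter
of that.  A dense layer holds `n·m + m`.  `count_layer_params()` and
`count_gate_params()` implement these formulas, and
`model_param_count()` counts the elements of the actually allocated
weight arrays of a built model; the test suite and the acceptance
script assert exact integer agreement between the two routes.  For the
reference univariate stack (1 → 256 → 128 → 64 → 1, dropout after the
first layer) the per-layer counts are 264,192 / 0 / 197,120 / 49,408 /
65 (total 510,785); the simple-RNN analogue gives 66,048 / 0 / 49,280 /
12,352 / 65.

### Why the network is implemented in-package

No deep-learning framework is available to this package's dependency
footprint, so the LSTM/RNN layers, backpropagation through time,
inverted dropout and Adam are implemented in vectorised base R
(`R/network.R`).  The implementation is deliberately minimal — fused
weights, Glorot-uniform initialisation, unit forget-gate bias, MSE
loss — and its gradients were verified against central finite
differences during development.  Training is seeded end to end
(initialisation, batch shuffling, dropout masks), so a fixed seed
reproduces the loss trace and the fitted weights exactly; inference
never applies dropout and is deterministic.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `window_length` | 200 samples | input window of the univariate filler; longer than one diurnal period (144) so a full cycle is always in view |
| `units` | 256/128/64 | reference stack; powers of two, tapering toward the scalar output |
| `dropout` | 0.2 after the first recurrent layer | presence follows the reference model summary; the rate is a conventional default (the source states presence, not rate) |
| `epochs` | 100 | reference training budget |
| `batch_size` | 100 | reference batch size |
| `learning_rate` | 1e-3 | Adam at its conventional default; the optimiser is unspecified in the source, so a standard adaptive first-order method is used |
| `gradient` (fusion) | 0.05 | weight decrement of the decreasing scheme; 20 levels from 1.00 to 0.05 |
| covariate `window_length` | 144 (one day) | the covariate model's input span; unstated in the source, chosen to cover one full diurnal covariate cycle |
| covariate dropout | keep-probability 0.8 | "dropout weight 0.8" read as keep-probability (drop fraction 0.2); the opposite reading is one configuration flag away |

Normalization is min–max to [0, 1], fitted on training segments only
and shared by the forward and reverse models of one experiment — the
minimal choice compatible with sigmoid/tanh gates.  Indexing is 1-based
with inclusive `(start, length)` gaps, so the prose range
"1001 to 1200" is `gap_spec(1001, 200)`.

### Numerical choices and degenerate inputs

* The decreasing-weight schedule defines 20 weight levels but a gap may
  have any length; the gap is partitioned into 20 consecutive blocks of
  equal size, remainders to the earliest blocks.  This preserves the
  printed endpoints (1.00, 0.00) and (0.05, 0.95) and the monotone
  0.05 staircase.  Per-index linear interpolation of the weights is a
  plausible alternative the source does not rule out; the blockwise
  mapping was chosen because it reproduces the printed level set
  exactly.  For gaps shorter than 20 the earliest levels are used once
  each.
* The recursion feeds predictions back verbatim in normalized space —
  no clipping.  Out-of-band excursions are part of the studied
  error-accumulation behaviour and are reported, not hidden.
* The segmented scheme splits at `ceiling(L/2)`; a length-1 gap takes
  its single value from the forward fill.  The junction discontinuity
  is expected and deliberately not smoothed.
* Min–max fitting rejects constant segments (zero range); training
  windows reject any missing value; a fill request without
  `window_length` observed values on its run-up side is rejected naming
  the deficient side.
* ARMA/ARIMA baselines: orders are unstated in the source, so they are
  AICc-selected over a `(p ≤ 5, q ≤ 5)` grid (`d` fixed at 0 for ARMA;
  for ARIMA chosen by repeated Phillips–Perron tests up to `d = 2`),
  with the chosen order logged in the result's provenance.
  Interpolation baselines use both flanks (gap bridged between known
  segments); forecasting baselines use only the pre-gap flank.

## The synthetic world

The study's sensor record is not deposited, so the package carries a
seeded generator (`simulate_stem_moisture()`) that emulates its stated
characteristics: 144 samples/day, values fluctuating within 43–57 %
around a 50 % base level, regular diurnal oscillation.  The signal is

    base + A·sin(2π t / spd + φ) + slow drift + AR(1) noise,

clipped last to the physical band, with defaults A = 5 %, drift
amplitude 1.5 % (spline-interpolated knots every ~3 days), noise
sd 0.3 % with lag-1 autocorrelation 0.7 and a seeded random phase.
Amplitude and noise defaults are not stated in the source; they were
chosen once as values a field scientist would call realistic for a
healthy tree in its stable growth period (diurnal swing a few percent,
sensor noise well under 1 %) and produce series visually comparable to
the published record.  Covariates are built as
`ρ·standardized(target) + √(1−ρ²)·noise`, rescaled to physical ranges
(AH around 70 ± 12 %, clipped to [0, 100]; PAR around 600 ± 300
µmol m⁻² s⁻¹, rectified at 0; ST around 20 ± 3 °C), with default
correlations AH +0.57, ST +0.29, PAR −0.30 from the published
stem-moisture/micro-environment correlation table.

What the generator does **not** emulate: asymmetric sunrise/sunset
shapes, weather fronts, irrigation events, sensor drift or
multi-tree structure.  A green test on this world establishes that the
*procedures* behave as described (recursion accumulates error, fusion
reduces it, covariate filling does not accumulate); it does not certify
error magnitudes on real sensor data.

## Scaled test world

Training the 510k-parameter reference stack (window 200, 100 epochs)
many times is far outside a test suite's CPU budget with a plain-R
training loop, so the stochastic properties are exercised on a
proportionally scaled world fixed once in the test helpers: 48
samples/day, window 48 (one day), a 96-sample central gap with 480
observed samples per side (the same 5:1 train:gap ratio), 32/16-unit
two-layer stacks with dropout 0.2, 40 epochs, Adam at 5e-3, batch 100.
Orderings asserted on this world (decreasing-weight fusion ≤ forward
fill; LSTM ≤ simple RNN; error growth along the recursive fill) are
averaged over seeds fixed a priori.

One direction claimed for the full-scale experiment does **not**
reproduce in this synthetic world: enlarging the training history 2.5×
(480 → 1200 points per side) does not improve the bidirectional fill
here, because a 480-point flank already identifies the simple
sinusoid-plus-noise process and the slow drift makes older data mildly
misleading about the gap-local level.  The corresponding acceptance
test states the claimed direction and is expected to fail on this
world; the package does not weaken the generator or the threshold to
mask that.

## Known limitations

* One contiguous gap per fill call; callers iterate for multi-gap
  records.  No resampling: non-uniform cadence is rejected, not
  repaired.
* No uncertainty quantification; fills are point estimates.
* The in-package trainer is single-threaded plain R: adequate for the
  scaled world and small production gaps, but training the full
  reference stack at window 200 takes hours, not minutes.  The
  architecture and accounting are framework-faithful, so weights-level
  results port to any standard recurrent implementation.
* Covariate filling assumes the covariates are themselves complete over
  the gap; filling the covariates is out of scope.
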