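# stemfill

Bidirectional recurrent gap filling for plant stem-moisture (and other
diurnal sensor) time series.

## The problem

Stem-moisture sensors sample volumetric water content every 10 minutes
(144 samples/day).  Equipment failures leave *long contiguous gaps* —
hundreds of samples, longer than a diurnal cycle — that interpolation
cannot bridge: splines fit the flanks, not the daily oscillation inside
the gap.  `stemfill` is for ecophysiologists and sensor-network
operators who need those gaps filled with the series' own dynamics.

## The method

A stacked LSTM one-step forecaster is trained on the observed flank and
the gap is filled recursively: a window of the `w` values before the
gap predicts the next value, the prediction is appended, the oldest
value dropped, and the window pushed until the gap is covered.  Error
accumulates along the recursion, so a second model is trained on the
time-reversed post-gap flank and the two directional fills `x_i`
(forward) and `y_i` (reverse) are fused per index,

    z_i = a_i * x_i + b_i * y_i,   a_i + b_i = 1,

with equal weights (0.5/0.5), a decreasing staircase (`a_i` from 1.00
down to 0.05 in 0.05 steps, `b_i` complementary — accurate-end weighting
in both directions), or a hard half/half segmented split.  Per-point
errors are summarised as the relative error `e = |x_p − x| / x`
(maximum, minimum, MAPE, threshold proportions) plus MAE/RMSE in
channel units.

Also included:

* **Analytic parameter accounting** for the recurrent stacks
  (`Param_LSTM = 4((n+m)m + m)` per layer, simple RNN exactly 1/4 of
  it, dense `nm + m`), cross-checked against the instantiated weight
  arrays.
* **Covariate filling**: a model mapping windows of air humidity, PAR
  and soil temperature to concurrent stem moisture fills gaps of
  unlimited length with no recursion and no error accumulation.
* **Classical baselines**: natural cubic spline, shape-preserving
  PCHIP, ARMA/ARIMA forecasts, and a gap-length sweep.
* **A seeded synthetic generator** of diurnal stem-moisture series with
  correlated covariates, so everything is testable without any
  download.

The LSTM/RNN layers, BPTT, dropout and Adam are implemented in
vectorised base R — the package has no deep-learning dependency.

## Worked example

```r
library(stemfill)
# a synthetic benchmark: 1056 samples at 48/day, 96-sample central gap
scen <- make_benchmark_scenario("custom", seed = 42, total_length = 1056,
                                gap_length = 96, samples_per_day = 48)
arch <- default_lstm_architecture(units = c(32, 16), dropout = 0.2,
                                  window_length = 48, batch_size = 100)
fill <- fill_bidirectional(arch, scen$masked, scen$gap,
                           scheme = "bidir_decreasing",
                           train_config = list(epochs = 40,
                                               learning_rate = 0.005),
                           seed = 42)
spline <- fill_interpolation(scen$masked, scen$gap, "spline")
compare_methods(list(lstm_forward = fill$components$forward,
                     lstm_reverse = fill$components$reverse,
                     bidir_decreasing = fill,
                     spline = spline),
                scen$truth)
```

```
Error statistics (max/min/MAPE relative x100; MAE/RMSE in channel units):
           scheme  n   maximum     minimum       mae       mape      rmse
     lstm_forward 96  4.050637 0.015162738 0.7372143  1.4640049 0.9177893
     lstm_reverse 96  6.244097 0.019026578 1.0882282  2.1249679 1.4143469
 bidir_decreasing 96  1.267394 0.009657178 0.2342936  0.4662557 0.2851492
           spline 96 35.456212 0.220663973 7.2404059 13.8627769 9.7922381

Share of points with relative error below threshold (%):
           scheme   lt_0.01   lt_0.02   lt_0.03   lt_0.04   lt_0.05
     lstm_forward 41.666667  66.66667  89.58333  98.95833 100.00000
     lstm_reverse 31.250000  57.29167  75.00000  84.37500  86.45833
 bidir_decreasing 92.708333 100.00000 100.00000 100.00000 100.00000
           spline  8.333333  14.58333  20.83333  25.00000  32.29167
```

Reading it: each directional fill is accurate near its own trained
flank and drifts toward the far end (MAPE 1.5–2.1 %); the
decreasing-weight fusion leans on whichever direction is locally
accurate and cuts MAPE to 0.47 % with every point inside 2 % relative
error, while the spline misses the diurnal oscillation entirely
(13.9 %).  MAE/RMSE are in percentage points of water content;
max/min/MAPE and the threshold shares are relative errors ×100.

For the full reference configuration (window 200, 256/128/64 units,
100 epochs, 10-min cadence) use `default_lstm_architecture()` and
`make_benchmark_scenario("paper-small")` unchanged — identical code,
longer training.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package at run time, the analytic
trainable-parameter counts of the reference LSTM and simple-RNN stacks
(per layer, plus the single-gate block), cross-checks each against the
element counts of the instantiated weight arrays of models built at the
given seed, and writes them as a flat JSON object keyed by target id.
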