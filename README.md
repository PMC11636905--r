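# glynarx — closed-loop NARX forecasting of blood glucose

Continuous glucose monitors (CGM) report blood glucose every 5 minutes.
Because insulin acts with a delay of tens of minutes to hours, glycemia
management — early hypo-/hyperglycemia alarms, pump dose adjustment —
needs forecasts far beyond the next sample. glynarx is a tested R
implementation of a nonlinear autoregressive (NARX) neural predictor
built for long horizons, for researchers and engineers working on CGM
analytics and closed-loop control.

## The method

The predictor maps a tapped delay line of the 20 most recent smoothed
glucose values through two tanh hidden layers (20 and 13 neurons) to a
linear output, the next value:

    ŷ(t+1) = F(y(t), y(t−1), …, y(t−19))

Glucose is the only input (it plays both the autoregressive and the
exogenous role). The network is trained **open-loop** (series-parallel):
sliding 40-sample windows — 20 inputs, 20 targets — are unrolled into
teacher-forced one-step pairs with true measurements in every tap, and
fitted by seeded full-batch Adam with validation-based early stopping.
The trained network is then **closed** into the parallel architecture:
its predictions are fed back through the taps, producing recursive
forecasts 1–20 steps ahead (prediction horizons PH = 5–100 min).

Each horizon is scored with RMSE (mmol/L), FIT
(`(1 − ‖G−Ĝ‖/‖G−Ḡ‖)·100`, Euclidean norm: 100 % = perfect, 0 % = mean
predictor), NPE (`√(Σ(G−Ĝ)²/ΣG²)·100`), and Clarke error-grid zone
percentages (A accurate … E dangerous, boundaries in mg/dl at
18.0182 mg/dl per mmol/L). A seeded synthetic CGM generator (circadian
drift, post-meal excursions, AR(1) sensor noise, optional dropouts)
makes the whole pipeline reproducible without external data.

## Worked example

```r
library(glynarx)

sim <- generate_profile(sim_config(days = 5, seed = 2))
res <- train_glucose_predictor(sim$times, sim$values, n_test = 500,
                               config = narx_config(seed = 2),
                               tc = train_config(seed = 2))
ev <- evaluate_horizons(res$model, res$test)
print(ev$metrics, digits = 4)
#>   ph_min npe_percent rmse_mmol_per_l fit_percent
#> 1     15       1.488          0.1254       91.37
#> 2     30       4.177          0.3524       75.82
#> 3     45       7.792          0.6577       54.97
#> 4     60      11.769          0.9940       32.09
#> 5     90      17.914          1.5148       -2.97
#> 6    100      19.449          1.6452      -11.63
print(ev$zones[["100"]])
#> <zone_summary> n = 461 | A 72.89%  B 27.11%  C 0.00%  D 0.00%  E 0.00%
```

The model simulates 5 days of CGM data, holds out the leading 500
samples for testing and trains on the remaining ~3 days. RMSE grows with
the horizon as recursive predictions compound, yet every point at the
100-minute horizon stays in the clinically acceptable Clarke zones A/B.
FIT turning negative at long horizons means the forecast explains less
variance than the test-set mean there — the persistence baseline is the
fairer reference for forecasting skill, and the network beats it at
every horizon:

```r
pb <- persistence_baseline(res$test)
pb$metrics$rmse_mmol_per_l
#> [1] 0.4164 0.8093 1.1626 1.4672 1.9307 2.0468   # vs 0.1254 … 1.6452 above
```

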