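---
title: "Closed-loop NARX forecasting of blood glucose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop NARX forecasting of blood glucose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glynarx)
```

## The problem

Continuous glucose monitors (CGM) deliver a blood glucose reading every
5 minutes (288 samples/day). Insulin acts with a delay of tens of minutes
to hours, so closed-loop glycemia management — early hypo-/hyperglycemia
alarms, pump dose adjustment — needs forecasts well beyond the next
sample. glynarx implements a nonlinear autoregressive (NARX) neural
predictor designed for long horizons: it is trained *open-loop*
(series-parallel) on true measurements and then *closed* into the
parallel architecture, feeding its own predictions back through the delay
taps to forecast recursively 1–20 steps (5–100 minutes) ahead.

## The model

Let $y(t)$ be the smoothed glucose signal. The network is a fully
connected mapping from a tapped delay line of the 20 most recent values
to the next value,

$$\hat y(t+1) = F\big(y(t), y(t-1), \dots, y(t-19)\big),$$

with two tanh hidden layers of 20 and 13 neurons and a linear output.
Glucose is the only input: it serves as both the autoregressive series
and the exogenous channel of the general NARX form, so the two tap lines
merge into a single 20-tap delay line. Inputs and targets are scaled
affinely from the training range onto $[-1, 1]$ to match the tanh units;
the scaler is fit on training data only (fitting on test data would
leak).

**Open-loop training (series-parallel).** Training slides a 40-sample
window over each uniform segment: 20 input samples, 20 target samples,
stride 1. Each window is unrolled into 20 one-step pairs — pair $k$ uses
samples $[k, k+19]$ as taps and sample $k+20$ as target — so every tap
vector holds *true* measurements (teacher forcing). We read the
open-literature 20-in/20-out training unit as this canonical one-step
teacher-forced scheme rather than as direct 20-step regression, because
the closed loop supplies the multi-step behaviour; the direct reading
remains available via `train_config(objective = "direct")` for
comparison.

**Loop closing and recursive prediction.** `close_loop()` re-tags the
trained network as the parallel architecture — identical weights, but
during forecasting each prediction is shifted into the tap buffer in
place of the oldest value. After $k$ steps the $k$ newest taps are
self-predictions; the forecast at horizon $PH = 5k$ minutes is step $k$.
The recursion depth is capped at 20 steps by default because beyond the
tap count the buffer holds only self-predictions.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_taps` | 20 | delay-line length; also the horizon cap (100 min) |
| `hidden` | 20, 13 | hidden layer sizes |
| `span` | 11 samples (55 min) | moving-average smoothing window |
| `max_gap` | 10 min | largest tolerated sensor gap inside a segment |
| `n_test` | 500 samples | leading samples reserved for evaluation |
| `learn_rate` | 0.005 | Adam step size |
| `max_epochs` / `patience` | 4000 / 200 | optimization budget and early stopping |
| `validation_fraction` | 0.15 | windows held out to pick the best epoch |

Smoothing uses a centered moving average whose window shrinks
symmetrically at the ends (`2 * min(i-1, n-i) + 1` samples), so the first
and last points pass through unchanged; this is the documented, frozen
endpoint rule, applied once per segment *before* the train/test split and
never across gap boundaries. Smoothing the CGM signal reduces the lag
between predicted and observed glucose, and the standard evaluation
protocol accordingly scores predictions against the smoothed test
series; passing the raw series to `evaluate_horizons()` gives the
raw-measurement variant.

**Optimizer.** Training minimizes the mean-squared one-step error with
full-batch Adam, seeded and therefore bit-reproducible. The conservative
step size (0.005) with a generous epoch budget and patience-200 early
stopping was chosen for reliable convergence on smoothed CGM windows;
the model returned is the one from the best validation epoch. Any
deterministic minimizer of the same loss would be a legitimate
substitute — the convergence contract is the training report, not the
algorithm.

**Gap handling.** Sensor dropouts break the autoregressive taps, so raw
traces are cut wherever consecutive timestamps differ by more than
`max_gap` (default twice the sampling period: one missed reading is
tolerable, more is not). Segments shorter than one 40-sample window are
discarded rather than padded — padding would fabricate data. Windowing
never crosses a segment boundary. With multiple retained segments the
leading `n_test` samples (in segment order) form the test set.

## Evaluation

For each horizon in the default sweep (15, 30, 45, 60, 90, 100 min) the
evaluator slides over the test series with stride 1, feeds the 20 true
values before each position into the closed network, recursively predicts
$k$ steps and pairs the step-$k$ prediction with the true value $k$
samples ahead. Three statistics summarize each horizon:

- **RMSE** (mmol/L): $\sqrt{\tfrac1N\sum_i (G_i - \hat G_i)^2}$;
- **FIT** (%): $\big(1 - \lVert G - \hat G\rVert / \lVert G - \bar G\rVert\big)\times 100$
  with the Euclidean norm — 100 % is perfect, 0 % is the mean predictor,
  negative values (worse than the mean) are reported unclipped;
- **NPE** (%): $\sqrt{\sum_i(G_i-\hat G_i)^2 / \sum_i G_i^2}\times 100$.

The Euclidean reading of the FIT norm is the one under which its two
anchor statements — 0 % for the mean predictor, 100 % for perfection —
hold exactly; both are verified in the test suite and recomputed by
`scripts/acceptance.R`.

Clinical accuracy uses the Clarke error grid: each (reference,
predicted) pair, converted to mg/dl at 18.0182 mg/dl per mmol/L (the
molar-mass convention; 18.0 and 18.016 also circulate, hence the frozen
constant), is assigned to zone A (accurate), B (benign), C
(overcorrection), D (dangerous failure to detect), or E (hypo/hyper
treatment confusion). The grid boundaries are the standard published
rule set, evaluated in the fixed precedence order A, E, C, D, else B so
that boundary ties resolve deterministically; the tests sweep the whole
integer grid ref, pred in [0, 400] mg/dl against an independent
re-implementation to confirm the rules partition it exactly.

## The synthetic CGM generator

Real pediatric type-1 CGM study data cannot ship with the package, so
`generate_profile()` emulates its structure: 5-minute sampling, glucose
mostly within 3.5–15.5 mmol/L, a 24-h circadian sinusoid (amplitude
1 mmol/L around a 7 mmol/L baseline), three post-meal excursions per day
(gamma-like pulses $m\,(\Delta t/\tau)\,e^{1-\Delta t/\tau}$ peaking at
height $m$ = 2–6 mmol/L a rise time $\tau$ = 30–60 min after onset), and
AR(1) sensor noise ($\rho = 0.8$, stationary sd 0.15 mmol/L), clamped to
[2.2, 22.2] mmol/L. The RNG is R's default Mersenne-Twister; a seed
fixes the series bit for bit. `inject_gaps()` punches sensor dropouts
for exercising the segmentation path.

The generator claims statistical resemblance — range, smoothness, meal
excursions, noise persistence — not physiological fidelity: there is no
insulin dynamics, no glucose–insulin feedback, no sensor drift or
calibration artefacts, and meal times are schematic. Tests passing on
synthetic data therefore demonstrate that the pipeline, training and
evaluation machinery behave correctly and that the network learns real
temporal structure; they do not certify clinical accuracy on patient
data, whose error tables must be reproduced on the real series.

## Numerical choices and degenerate inputs

- Scaling endpoints map the training min/max to exactly ±1; values
  outside the range map linearly outside $[-1, 1]$, never clipped.
- A constant training set has no scale and is rejected
  (`fit_scaler()` errors) — as are constant measured sequences in FIT
  and all-zero measured sequences in NPE, whose denominators vanish.
- Model files are JSON at 17 significant digits, which round-trips IEEE
  doubles exactly: a reloaded model reproduces every prediction bit for
  bit. Files carry a schema tag; unknown versions are refused loudly.
- Non-finite training loss aborts with a diagnostic rather than
  returning a silently broken model.
- Training, initialization, the validation split and the generator all
  draw from seeded RNG scopes that restore the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises training at desk scale: sinusoid capacity checks use
620-sample series (about 2 simulated days) over three seeds, and the
end-to-end superiority check trains on 5 simulated days per seed — the
first 500 samples held out for testing, the remaining ~940 (about 3
days) for training, mirroring the leading-500 protocol of the full-scale
study design. These sizes give stable results across seeds while keeping
a full run of the suite comfortable on one CPU.

## Known limitations

- Topology is fixed at taps → hidden → hidden → 1 (sizes configurable);
  no insulin or meal covariates — glucose is the only input by design.
- Horizons beyond `n_taps` steps are refused by default: every tap would
  be a self-prediction.
- No gap imputation: data on either side of a dropout are kept apart.
- Reported study-scale error tables depend on the original patient data
  and an unreported optimizer; they are context for the method, not
  quantities this package can regenerate from first principles.
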