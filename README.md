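# mmgforce

Estimating dynamic skeletal-muscle force from multichannel mechanomyography
(MMG). MMG is the low-frequency mechanical vibration of a contracting
muscle, recorded on the skin with accelerometers; for the knee extensors
(rectus femoris RF, vastus lateralis VL, vastus medialis VM) it carries
enough information to regress the extension force continuously — if two
practical problems are handled: **cross-talk** (each sensor picks up
neighbouring muscles) and the **temporal structure** of the force signal.

`mmgforce` is a complete pipeline for researchers in biomechanics and
rehabilitation engineering:

* **Cross-talk quantification** — the lag-weighted normalized
  cross-correlation
  `R(τ) = Σₙ x(n) y(n+τ) / (√(a·b)·ω(τ))` with `a = Σx²`, `b = Σy²` and
  the overlap weight `ω(τ) = (max(N,M) − |τ|)/max(N,M)`; the peak
  coefficient (PCCC) per muscle pair is classified low (< 0.30), moderate
  (0.30–0.70) or high (> 0.70).
* **Windowed features** — a 25-descriptor bank (time, frequency,
  time–frequency, nonlinear) over 250 ms sliding windows, screened against
  the force target by grey relational analysis (Deng grades, ρ = 0.5).
* **Models** — a single-layer LSTM regressor (full BPTT, Adam on RMSE,
  compiled core), with BPNN and RBF ε-SVR baselines, scored by
  NRMSE = RMSE/(y_max − y_min), fractional MAPE and Pearson R.
* **Hyper-parameter search** — canonical grey wolf optimizer plus an
  improved variant (chaotic initialization, cosine convergence factor,
  greedy selection), tuning hidden size ∈ [50, 400] and learning rate
  ∈ [0.001, 0.01].
* **Synthetic recordings** — a generator with a known mixing (cross-talk)
  matrix and a known force–activation law, so every claim the pipeline
  makes is testable against ground truth.

## Worked example

Generate a synthetic dynamic-contraction trial, quantify cross-talk, build
and screen features from the cleanest channel, and fit the LSTM:

```r
library(mmgforce)

cfg <- sim_config(duration = 20, seed = 42)
rec <- trim_edges(denoise_recording(generate_recording(cfg)), 2, 2)
rec
#> MMG recording: 3 channel(s) [RF, VL, VM], 16000 samples @ 1000 Hz (16.0 s)
#>   force: 0.272-0.574 (fraction of maximum)

pairwise_crosstalk(rec)
#> Cross-talk report (PCCC over +/- lag window)
#>  pair ch1 ch2   pccc peak_lag_s    class
#>   MP1  RF  VL 0.5550     +0.001 moderate
#>   MP2  RF  VM 0.6075     +0.000 moderate
#>   MP3  VL  VM 0.2839     +0.000      low
```

The adjacent pairs (MP1, MP2) show moderate cross-talk while the
non-adjacent pair is low, and VL is the least contaminated channel — so its
feature combination ("F2") is the preferred input:

```r
tab <- build_feature_table(rec, channels = "F2",
                           spec = window_spec(250, 50, 1000))
idx <- chrono_split(nrow(tab$X))          # chronological 90/10 split
sc  <- screen_features(tab, train_idx = idx$train)
sc
#> GRA screening (rho = 0.5, rule = top_k): kept 10 of 25 features
#>   top grades:
#>     VL:var       0.7926
#>     VL:tp        0.7923
#>     ...

st <- zscore_fit(tab$X[idx$train, sc$mask])
X  <- zscore_apply(tab$X[, sc$mask], st)
ymu <- mean(tab$target[idx$train]); ysd <- sd(tab$target[idx$train])

fit <- mmg_lstm(X[idx$train, ], (tab$target[idx$train] - ymu) / ysd,
                hidden = 100, lr = 0.005, epochs = 250, seed = 1)
pred <- predict(fit, X[idx$test, ]) * ysd + ymu
evaluate_force(pred, tab$target[idx$test])
#> NRMSE = 0.1671, MAPE = 0.0520, R = 0.9803 (n = 32)
```

So on the held-out final 10% of windows the estimated force tracks the
observed force with a correlation of 0.98 and an error of 17% of the
observed range (5.2% mean absolute deviation relative to the force level).

The experiment drivers automate this over feature combinations F1–F7
(`run_combination_experiment()`) and over the four models BPNN, IGWO-SVR,
LSTM and IGWO-LSTM (`run_model_comparison()`), producing mean ± SD tables
via `report_to_table()`. Hyper-parameter tuning is available directly as
`tune_lstm()` / `tune_svr()` on top of `gwo()` / `igwo()`.

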