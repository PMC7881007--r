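# pwcnet

Few-shot classification of pulse wave contours (PWC) — the quasi-periodic
waveforms recorded by photoplethysmography (PPG) or wrist pressure sensors —
into two morphology classes (normal-like vs abnormal-like). Labelled pulse
wave corpora are small, so the package pairs a conservative signal-
conditioning front end with a deliberately small-parameter network, and
ships a synthetic waveform generator so the entire stack can be trained and
tested without clinical data.

## What is inside

**Preprocessing.** Empirical mode decomposition (EMD) with endpoint-anchored
spline envelopes decomposes each record into intrinsic mode functions; the
record is rebuilt from the IMFs whose dominant frequency lies in the pulse
band (0.4–20 Hz by default), which removes respiration wander (~0.2–0.3 Hz),
mains pickup (50/60 Hz) and instrument noise (> 90 Hz). A Pearson retention
gate discards any record whose denoised version correlates with the original
at ≤ 0.93. Beats are segmented trough-to-trough using the systolic peaks as
reference, resampled to 235 points, min–max normalised, and grouped into
windows of N = 5 consecutive cycles.

**Model.** Three parallel feature branches feed a softmax head:

* a bidirectional recursive layer built from a single-forgetting-gate
  recurrent unit,

  f_t = σ(W_fh·h_(t−1) + W_fx·x_t + b_f),  c̃_t = tanh(W_ch·h_(t−1) + W_cx·x_t + b_c),
  c_t = f_t ⊙ c_(t−1) + (1 − f_t) ⊙ c̃_t,  h_t = tanh(c_t),

  with 2h(h+x+1) parameters — exactly **half an LSTM cell** (17 152 at
  h = 32, x = 235). Forward and reverse units are coupled through a
  Bernoulli mask (keep probability 0.5 in training);
* a **periodic** 1-D conv branch on each 235-sample beat
  (conv 7/5/32 → pool 3/2 → conv 5/5/64 → pool 3/1 ⇒ 128 features);
* a **rhythm** 2-D conv branch on the 235 × 5 time-by-beat map
  (conv 7×3 → pool → conv 5×3 → pool ⇒ 128 features).

The 64 + 128 + 128 = 320 features pass through FC(320→32)+ReLU, FC(32→2)
and softmax; training is minibatch Adam (batch 64) on cross-entropy with
analytic backpropagation implemented in-package, reproducible from a single
seed. Evaluation reports accuracy, sensitivity, specificity, precision and
F1 from the confusion counts, with the abnormal class positive.

## Worked example

```r
library(pwcnet)

ds <- make_dataset(20, n_beats = 40, fs = 200,
                   noise = noise_preset("cnbp"), seed = 42)
pp <- preprocess_records(ds$records)   # EMD + gate + segmentation + windows
da <- windows_to_array(pp$windows)
mean(pp$provenance$kept)               # 0.975  (39/40 records pass the gate)
dim(da$x)                              # 273 windows x 5 beats x 235 samples

sp <- split_windows(da$y, seed = 1)    # stratified 4:1 split
fit <- train_model(da$x[sp$train, , , drop = FALSE], da$y[sp$train],
                   epochs = 20, seed = 1,
                   val_x = da$x[sp$test, , , drop = FALSE],
                   val_y = da$y[sp$test])
fit
#> <pwc_fit> 20 epochs, final train loss 0.0304, test acc 0.982

pred <- predict(fit, da$x[sp$test, , , drop = FALSE])
head(pred, 3)
#> # A tibble: 3 × 3
#>   .pred_class .prob_normal .prob_abnormal
#>         <int>        <dbl>          <dbl>
#> 1           0        0.929        0.0713
#> 2           0        0.998        0.00238
#> 3           0        0.994        0.00597

evaluate_predictions(pred$.pred_class, da$y[sp$test])
#> # A tibble: 1 × 5
#>     acc   sen   spe   pre    f1
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0.982 0.964     1     1 0.982
```

The held-out windows are classified at 98% accuracy: one abnormal window is
missed (sensitivity 0.964), no normal window is false-alarmed (specificity
1). `tidy(fit)` returns the per-epoch loss/accuracy log, `glance(fit)` a
one-row summary including the 73 698-parameter count, and `autoplot(fit)`
the training curves. `unit_cycle_sweep()` repeats training for window sizes
N ∈ {2,…,6} and tabulates the five metrics per N.

A command-line front end with `simulate`, `preprocess`, `train`, `evaluate`
and `sweep` subcommands is installed at `inst/cli/pwcnet.R`.

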