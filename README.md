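# bsr — Bowel Sound Recognition with a Branchformer Encoder

Bowel sounds are brief acoustic events produced by gas and fluid movement
during gastrointestinal peristalsis. Detecting them automatically in
abdominal audio underpins non-invasive monitoring of gut motility, but the
signals are sporadic, wide-band, and noisy, and labelled clinical data is
scarce. `bsr` is an R toolkit for the resulting binary task — *does this
2-second clip contain a bowel-sound event?* — aimed at researchers who want
a complete, reproducible, dependency-light pipeline they can run and extend
on a laptop.

The package provides:

* **Preprocessing** — WAV/CSV ingestion, segmentation with overlap-based
  labelling, peak normalisation to `[-1, 1]`, pre-emphasis
  `y[t] = x[t] − α·x[t−1]`, band-limited resampling, and window framing
  (`n_frames = 1 + ⌊(L − fl)/fs⌋`; Hanning/Hamming/rectangle).
* **Acoustic features** — log mel-spectrum (HTK mel scale), MFCC
  (orthonormal DCT-II of the log-mel vector), and LPC
  (autocorrelation method, Levinson–Durbin), each regularised to a fixed
  feature length `tl`.
* **The Branchformer encoder** — `N` identical blocks, each running a
  global and a local branch in parallel on the hidden sequence
  `X ∈ R^{T×d}` and merging them:

  ```
  Y_G = Dropout(MHSA(LN(X)))                      # global: self-attention
  Z   = GELU(LN(X) U)                             # local: cgMLP
  [A B] = Z
  CSGU(Z) = A ⊙ DwConv(LN(B))
  Y_L = Dropout(CSGU(Z) V)
  Y   = X + Concat(Y_G, Y_L) W                    # merge + residual
  ```

  with a stride-2 convolutional frontend, branch dropout during training,
  and a 2-class head. A weighted-average merge with learned softmax
  weights is available as an alternative to concatenation.
* **Baselines** — compact CNN, LSTM, CNN+LSTM, and a full ResNet-34
  (stages 3-4-6-3) behind the same feature-in/probabilities-out contract.
* **Fine-tuning strategies** — FP (full-parameter), LP1 (freeze extractor,
  replace last classification layer), LP2 (freeze extractor, remove last
  three layers), applied as declarative surgery over an abstract
  pretrained-encoder interface.
* **Evaluation** — stratified splits, accuracy `ACC = (TP + TN)/(P + N)`,
  a resumable one-factor-at-a-time sweep runner (225-cell replication
  grid), and exact/midrank Mann–Whitney U comparisons between model
  families.
* **Synthetic data** — 2-second clips with band-limited noise bursts
  (100–1000 Hz, attack–decay envelope) over white/pink background at a
  controlled SNR, written as WAV + CSV exactly like a real corpus, so the
  whole pipeline runs with no downloads.

All models train through the package's own reverse-mode autodiff engine
(tape-based, with hand-derived backward rules for attention, convolutions,
batch norm and LSTM; every rule is finite-difference-checked in the test
suite). There is no GPU path; everything is sized for desk-scale
experiments.

## Worked example

Train a small Branchformer to separate synthetic bursts from background at
10 dB SNR:

```r
library(bsr)

segs  <- synthetic_segments(synth_config(n_clips = 400, snr_db = 10, seed = 11))
feats <- lapply(segs, function(s)
  extract_features(pre_emphasize(peak_normalize(s$clip)), "mel",
                   fl = 1024, fs = 441, tl = 164, window = "hamming"))
y  <- vapply(segs, function(s) s$label, integer(1))
sp <- split_dataset(seq_along(segs), seed = 11, labels = y)
i  <- sp$indices

model <- init_branchformer(40, encoder_config(d = 32, n_blocks = 2,
                                              n_heads = 4, d_inter = 128),
                           seed = 11)
fit <- train_model(model, feats[i$train], y[i$train],
                   feats[i$validation], y[i$validation],
                   control = train_control(epochs = 25, batch_size = 32,
                                           patience = 8),
                   seed = 11)
glance(fit)
#> # A tibble: 1 × 6
#>   family       n_params epochs final_train_accuracy best_val_accuracy  seed
#>   <chr>           <int>  <int>                <dbl>             <dbl> <int>
#> 1 branchformer    36162      9                0.997                 1    11

evaluate_model(fit, feats[i$test], y[i$test])$accuracy
#> [1] 1
```

`best_val_accuracy = 1` and test accuracy 1 mean every held-out clip was
classified correctly: at this SNR the mel-energy footprint of a burst is
strong, so the run verifies the pipeline end to end (about a minute on one
CPU) rather than stressing model capacity. `tidy(fit)` returns the
per-epoch history and `autoplot(fit)` plots it; `sweep_grid()` +
`run_sweep()` scale the same loop across preprocessing settings and model
families, and `compare_families()` annotates pairwise Mann–Whitney U
results.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/bsr simulate --n 200 --sr 44100 --snr 10 --seed 7 --out data/
Rscript inst/cli/bsr sweep --cells sr --models cnn,branchformer --features mel --out sweep.csv
Rscript inst/cli/bsr finetune --strategy LP1
```

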