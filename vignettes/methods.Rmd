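---
title: "Channel-wise correlation features and stacked LSTM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-wise correlation features and stacked LSTM: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`chanwise` classifies short windows of multichannel EEG into emotion
categories (binary valence or arousal, the four valence–arousal
quadrants, or three categorical film-clip classes). The representation
is functional connectivity rather than amplitude: a window of
`L·K·N` samples per channel is reduced to segment means
(`S[c,k,n]`, the mean of `L` consecutive samples), and at each of `N`
time steps the `C × C` matrix of Pearson correlations between all
channel pairs over their `K` segment means is computed. Each matrix is
symmetric with unit diagonal, so only its `C(C−1)/2` strictly-upper
entries are kept, in a fixed row-major order. The `N`-step sequence of
flattened matrices is the input to a two-layer stacked LSTM; the last
time step's hidden state in the second layer passes through dropout and
one fully connected softmax layer.

Two assumptions drive the design. First, inter-channel correlation
patterns are highly subject-specific and stable across stimuli, so a
single correlation matrix mostly identifies the *person*; the emotion
signal is a smaller, time-varying perturbation on top. Second, because
correlations are bounded in `[−1, 1]`, the network needs no input
normalization or batch-normalization layer — only dropout regularizes
the head.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `L` | 2 | samples | segment-mean length; larger `L` denoises but consumes more signal per window. Hard floor 1; 2 is the selected setting. |
| `K` | 8 | segments | points per correlation estimate; must be ≥ 2. Small `K` keeps windows short at the cost of noisy correlations (sd ≈ 1/√(K−1) ≈ 0.38 at K = 8). |
| `N` | 10 | time steps | LSTM sequence length; accuracy degrades when too few steps are observed. |
| `hidden_dim` | 256 | – | LSTM state size; 256 is the published configuration, and the learned 256-dim "emotional features" are what PCA visualizes. Tests use 8–32 for speed. |
| `dropout_p` | 0.5 | prob. | only regularizer, applied to the FC input, disabled at inference. |
| `learning_rate` | 0.001 | – | RMSProp step size. |
| `batch_size` | 240 | examples | mini-batch size under seeded shuffling. |

At 128 Hz the default window covers `2·8·10/128 = 1.25` s; at 200 Hz,
0.8 s. Sliding-window augmentation strides by `L·K` samples — exactly
one correlation matrix's worth — so adjacent windows share `N−1` of
their `N` features and a trial of `M` samples yields
`⌊(M − L·K·N)/(L·K)⌋ + 1` examples.

## Numerical choices

- **Flattening order** is row-major over the strict upper triangle
  (`(1,2), (1,3), …, (2,3), …`). Any fixed order would do for learning;
  fixing one makes feature files portable, and it is recorded in each
  feature directory's `schema.json`.
- **Degenerate channels.** If a channel's `K` segment means are
  constant, its Pearson row is 0/0. Convention: off-diagonals 0,
  diagonal 1, with a warning — a flat-lined or reference channel then
  contributes no spurious structure instead of poisoning the window.
- **Clipping.** Correlations are clipped to `[−1, 1]` only to absorb
  floating-point overshoot; the sample-covariance normalization
  (population vs sample) cancels in the ratio, which the oracle tests
  confirm to 1e−12.
- **Rating ties.** Self-assessment ratings above 5 are "high", below 5
  "low". A rating of exactly 5 is unassigned by the published rule; the
  package maps it to "low" by default so every trial stays usable, and
  offers `ties = "drop"` for discarding midpoint trials.
- **Trailing windows** that do not fill `L·K·N` samples are dropped;
  windows never span trial boundaries, so no correlation is ever
  computed across a stimulus change.
- **Optimizer constants.** RMSProp uses smoothing 0.9 and epsilon 1e−7
  (the usual framework defaults; only the learning rate is prescribed);
  both are stored in the `train_config` carried on the trained model.
  Weights initialize uniform in `(−1/√H, 1/√H)` from the run seed.
- **Determinism.** Initialization, batch order and dropout masks all
  derive from one seed, so a training run is bitwise reproducible on a
  single-threaded BLAS; a multi-threaded BLAS may perturb the last ulp
  through summation order, which is why reproducibility tests assert
  equality at 1e−12 rather than `identical()`.
- **Epoch budget.** The published work states no epoch count or stopping
  rule. Default here: a fixed budget returning final weights
  (`validation_fraction = 0`). Setting `validation_fraction > 0`
  activates best-validation-loss checkpointing and optional early
  stopping. The fixed-budget default was chosen so small CV folds do not
  silently lose a tenth of their training data; this inverts the
  "checkpoint by default" design suggestion, deliberately.

## The LSTM implementation

No deep-learning framework is available in the target environment, so
the two-layer stacked LSTM — forward pass, backpropagation through
time, and RMSProp — is implemented directly in R. All heavy operations
are BLAS matrix products over mini-batches, which at the package's
scales (batch ≤ 240, 10 time steps, hidden ≤ 256) leaves little for a
compiled kernel to win. Correctness rests on a gradient check: analytic
gradients of every parameter tensor agree with central finite
differences to 1e−6 on a small network in the test suite.

## What the synthetic generator emulates — and what it does not

Each synthetic subject gets a base correlation matrix drawn from a
random factor model (`cov2cor(WWᵀ + diag(u))`), giving structured,
person-specific connectivity. Each emotion class perturbs a sparse
random 10% of channel pairs; for two-class schemes the classes sit at
±`magnitude/2` on a shared support, so the between-class gap is exactly
`magnitude` (default 0.6) before projection back to the nearest valid
correlation matrix (eigenvalue clipping at 1e−3, diagonal
renormalization). Signals are AR(1)-smoothed Gaussian noise
(coefficient 0.5) mixed through the Cholesky factor of the target
matrix, plus white sensor noise (sd 0.2). AR(1) smoothing mimics EEG's
temporal autocorrelation and makes adjacent segment means realistically
dependent; white noise alone would satisfy the correlation-recovery
contract but with unrealistically independent segments.

The default configuration — 4 subjects, 2 trials per subject and class,
17 s trials at 128 Hz over 8 channels, about 2,000 sliding windows — is
the package's stated benchmark world and is not tuned per run.

The generator does **not** emulate: oscillatory band structure (alpha,
beta, gamma), nonstationarity within a trial, artifacts (blinks, muscle),
volume conduction or any biophysical forward model, or realistic
electrode geometry. A green end-to-end test therefore establishes that
the pipeline recovers planted correlation structure and that the
classifier learns correlation-space class differences — it says nothing
about accuracy on real EEG, which the restricted benchmark datasets
would be needed to measure.

Two quantitative caveats the tests make explicit:

- The `K = 8` sample correlation is biased toward zero for strong
  correlations, and AR(1) smoothing enlarges the effect; measured as
  ~0.06 at `|ρ| ≈ 0.7`. The recovery contract (mean feature within
  ±0.1 of the target) is checked over ~700 windows so Monte-Carlo noise
  is negligible against this bias.
- The subject-mixed split the published protocol uses lets windows of
  the same subject and trial fall on both sides of a fold. On synthetic
  data with strong subject structure, mixed-split accuracy exceeds
  subject-wise accuracy by a wide margin — the package reproduces the
  protocol (`random_mixed`, with a warning) and provides `subject_wise`
  as the honest alternative; a test asserts the inflation. Whether folds
  should be drawn over augmented windows or whole trials is likewise
  unspecified in the source protocol; splitting happens over whatever
  example list is passed, so trial-level splitting is available by
  windowing after the split.

## Known limitations

- No frequency-band features, differential entropy, or related-work
  representations; the correlation matrix is the only feature.
- The dataset-layout adapters cover the documented channel orderings and
  rates (32 ch / 128 Hz, 62 ch / 200 Hz) and the generic text loader,
  but the original datasets' binary containers cannot be read offline in
  this environment.
- Training at the full published scale (input 496–1891, hidden 256,
  tens of thousands of windows) is possible but slow in pure R; the
  shipped benchmarks run at reduced hidden size, which the acceptance
  criteria explicitly permit.
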