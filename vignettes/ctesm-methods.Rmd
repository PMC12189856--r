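---
title: "Methods: hybrid convolutional–attention–LSTM classification of resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid convolutional–attention–LSTM classification of resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Parkinson's disease (PD) disrupts oscillatory cortical activity, most
prominently in the beta band (13–30 Hz) of the cortico-basal-ganglia loop.
Resting-state EEG therefore carries a non-invasive class signal separating
PD patients from healthy controls (HC). `ctesm` implements a complete
frame-based classification pipeline for this problem: windowing, a
biologically informed per-frame feature representation, feature-level data
augmentation, and a hybrid convolutional / multi-head-attention / LSTM
classifier, together with a synthetic cohort generator so every stage is
testable without patient data.

# The feature representation

Each recording is cut into overlapping frames (default 2 s length, 1 s
overlap; trailing samples that do not fill a frame are dropped so all
frames share one spectral resolution). For every frame–channel pair the
extractor computes, in a frozen order:

1. **Band powers** (5): the *mean* power spectral density over the bins of
   each canonical band — delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30,
   gamma 30–45 Hz. The PSD comes from a Welch estimate with 1 s segments,
   50% overlap, periodic Hann taper, per-segment mean detrending. The
   per-bin *mean* (rather than the integrated band power) is the package's
   band-power definition; both differ only by a band-width factor.
2. **Beta/alpha power ratio**: the classic PD marker. A denominator at or
   below `1e-12` is floored there and the value flagged.
3. **Median frequency**: the smallest bin at which the cumulative PSD
   reaches half the total (ties resolve to the lower frequency by the
   `>=` convention).
4. **Spectral entropy** (bits): Shannon entropy of the PSD normalized to a
   probability distribution; zero bins contribute zero, so the value lies
   in `[0, log2(n_bins)]`.
5. **Wavelet level means** (6): mean absolute detail coefficient at each
   of 5 levels of a periodized Daubechies-4 (8-tap) DWT, plus the final
   approximation mean. At 500 Hz the detail bands roughly track the
   canonical EEG bands; family and depth are configurable. Odd lengths at
   any level are extended by repeating the final sample — the same
   convention as the reference implementation the test suite's frozen
   oracle values were computed with.
6. **Approximate entropy**: standard template-matching ApEn with `m = 2`
   and tolerance `r = 0.2 × SD` (population SD), the field's conventional
   parameters. The applied literature sometimes uses the same name for the
   Shannon entropy of an amplitude histogram; that reading is available as
   `apen_mode = "amplitude"` but is not the default, because the
   template-matching definition is what the term denotes and what the
   regularity interpretation ("lower = more predictable") requires.
7. **Skewness, kurtosis** (population moments, denominator `N`; kurtosis
   is *not* excess-adjusted, so a Gaussian scores ≈ 3) and
   **zero-crossing rate** (sign-changing adjacent pairs / `(N − 1)`).

Undefined features (moments of a flat channel, entropy of an all-zero
spectrum) are recorded as a sentinel (default 0) and flagged per
frame–channel; channels are never dropped. Under amplitude scaling by
`c > 0` the band powers scale by `c²`, the wavelet means by `c`, and all
remaining features are invariant — the suite property-tests this exactly.

# Augmentation

Each `channels × features` instance is expanded with `n_variants`
(default 50, a 51× expansion) synthetic matrices built by three steps:
additive zero-mean Gaussian noise (σ = 0.05, absolute feature scale; a
per-feature-standardized variant is available because an absolute σ is
scale-sensitive across heterogeneous features), a single amplitude scaling
drawn uniformly from [0.9, 1.1], and *dynamic modulation* — a per-entry
uniform perturbation of the deviation from the instance mean, re-centered
so the parent's mean is preserved exactly. The modulation step is the one
under-specified ingredient of the recipe; the implementation here (offset
∝ deviation-from-mean, bound `modulation_strength = 0.1`, exact
re-centering) is documented as this package's interpretation. Labels are
inherited; provenance (`is_synthetic`, `parent_id`) is kept per instance.

By default augmentation is applied to the **training partition only**.
Applying it before the split (`augment_scope = "all"`) is supported for
protocol fidelity with feature-level augmentation pipelines that expand
first and split second, but it leaks near-copies of training frames into
the test partition and inflates test metrics; the package treats the
leakage-safe order as the default.

# The classifier

The input to the network is one frame's `channels × features` matrix. The
stages, all hand-implemented with exact backpropagation (verified against
central differences in the test suite):

- **Convolutional front end**: two valid 1-D convolutions (+ReLU) along
  the electrode axis with the feature families as input channels, max
  pooling, then batch normalization (learnable scale/shift, running
  statistics for inference). The output is read as a sequence
  `T × D` with `T = floor((C − 2(k−1))/pool)` positions along the
  electrode-derived axis and `D = conv_filters[2]` model dimensions. The
  choice of the electrode-derived axis as the attention/LSTM sequence axis
  follows the reshape contract of the architecture; it is stated
  explicitly because the convolution axis is otherwise ambiguous.
- **Transformer block**: multi-head scaled dot-product self-attention
  `softmax(QKᵀ/√d_k)V` per head, heads concatenated and projected;
  residual connection and layer normalization; a position-wise
  feed-forward (ReLU affine then affine, width `ff_dim`); second residual
  + layer normalization. Layer normalization is implemented as plain
  per-position standardization over the feature axis *without* a learnable
  affine, matching the bare `(x − μ)/σ` form of the block's definition;
  `eps = 1e-8` keeps the row statistics exact to the `1e-6` contract the
  tests assert.
- **Dropout** (default rate 0.3) after the transformer block. This is the
  "regularization mechanism" the corresponding ablation removes; batch
  normalization stays in all variants because it is part of the
  convolutional stage proper.
- **LSTM head**: a standard LSTM (forget-gate bias initialized at 1) over
  the `T` positions from zero initial states; the final hidden state feeds
  a dense softmax layer. The no-LSTM ablation mean-pools the sequence into
  the dense head instead.

Training is mini-batch Adam (learning rate 1e-3) on categorical
cross-entropy, default 50 epochs at batch size 32, with 10% of the
training instances held aside for validation monitoring. Feature columns
are z-scored with training-set statistics stored in the model: the
feature families span ~6 orders of magnitude (band powers in squared
microvolts vs entropies in bits), and standardization is the standard
conditioning step for a network consuming them jointly. One integer seed
fans out to initialization, shuffling, splitting and dropout; prediction
runs in inference mode (running batch-norm statistics, no dropout), so
per-instance predictions are independent of batch composition.

All layer widths default small (filters 32/64, kernel 3, pool 2, 4 heads,
`d_k` 16, feed-forward 64, LSTM 64) so a single CPU trains in seconds to
minutes at the problem sizes below; every width is config-exposed.

# The synthetic cohort generator

`cohort_spec()`/`generate_cohort()` simulate the study conditions the
pipeline is designed for: two classes of multichannel resting-state EEG
(defaults: 40 channels, 500 Hz — a standard high-density 10–20 montage) in
which each subject's signal is a sum of

- one sinusoid per canonical band, frequency drawn uniformly from the band
  *interior* (10% edge margin) per subject, independent phase per channel,
  amplitude = baseline band amplitude × class multiplier × mild (±20%)
  channel jitter;
- a 1/f-shaped stochastic background (white noise FFT-shaped by
  `f^(−exponent/2)`, default exponent 1, default RMS 5);
- white Gaussian sensor noise (default SD 1).

Baseline band amplitudes (delta 20, theta 10, alpha 15, beta 6, gamma 3,
arbitrary microvolt-scale units) follow the usual descending resting-state
spectrum; no published amplitude scale was available to copy, so these are
conventional values, fixed once. The interior margin exists because a
component at a band edge is attributed to the neighbouring band at the
1 Hz analysis resolution, which would silently corrupt the intended class
construct (an "alpha" subject counted as beta-elevated). The class effect
is a per-band amplitude multiplier (default: PD beta × 2.5), optionally
restricted to a contiguous channel subset (`effect_channels`) — the
spatially localized variant emulates the topographic concentration of
Parkinsonian beta disruption over sensorimotor cortex, and it is the
variant under which the sequence axis actually carries class-relevant
positional structure (with a spatially uniform effect, mean-pooling the
sequence loses nothing and the LSTM cannot matter by symmetry).

Subjects use independent RNG streams derived from the spec seed by
counter, so cohorts are bit-reproducible and subjects independent. What
the generator does **not** emulate: physiological artifacts (blinks, EMG),
volume conduction / channel correlation structure, non-stationarity within
a recording, and medication or age covariates. Passing tests on this
generator therefore demonstrate the pipeline's mechanics and its
sensitivity to band-limited class effects — not clinical performance on
real recordings.

# Statistical screen and metrics

`channel_screen()` reduces each recording to per-channel subject means and
compares groups per channel with a pooled-variance t-test and a one-way
ANOVA. With two groups these are one test (`t² = F`); the pooled-variance
choice keeps that identity exact (Welch is available). Per-subject (not
per-frame) means are used as the statistical unit so the screen's p-values
rest on independent observations. p-values are reported raw, matching the
screening-table convention; Benjamini–Hochberg columns are optional.

`evaluate_predictions()` derives accuracy and macro-averaged
precision/recall/F1 from the confusion matrix (macro: robust to class
imbalance; micro and support-weighted variants by flag).

# Problem sizes and the acceptance experiment

The packaged acceptance experiment (also run by `scripts/acceptance.R`)
uses a desk-scale cohort chosen as this package's own study conditions: 10
subjects per class, 16 channels at 128 Hz (the full band structure fits
under the 64 Hz Nyquist), 30 s per recording (29 frames/subject, 580
instances), beta multiplier 2.5 expressed on channels 5–10, subject-wise
80/20 held-out split, default model, 50 epochs. The ablation comparison
averages over 3 seeds, each seed driving both the subject split and
training; the ordering assertion (full ≥ no-regularization ≥ no-LSTM)
carries a 0.02 tolerance for seed-level noise, fixed before the experiment
was first run at these conditions. Held-out accuracy at this scale is
dominated by whole-subject flips (a test partition holds 4 subjects ×
29 frames), which is why seed-averaged numbers accompany the single-seed
report in the acceptance output.

# Numerical choices

- Welch: periodic Hann taper, one-sided density with DC/Nyquist not
  doubled, per-segment mean detrending so total power ≈ variance.
- Median frequency tie-break: first bin reaching half power.
- Division floors: beta/alpha `epsilon = 1e-12`; undefined-feature
  sentinel 0 + flag.
- DWT depth limit `floor(log2(n/(L−1)))` for filter length `L`; deeper
  requests are validation errors.
- ApEn counts include self-matches (the standard estimator's convention),
  and the test suite pins the implementation to an O(n²) loop oracle at
  `1e-10`.
- Batch norm: momentum 0.9 running statistics, `eps = 1e-5`; layer norm
  `eps = 1e-8` (see above); Adam β₁ = 0.9, β₂ = 0.999, `eps = 1e-8`.
- EDF output quantizes to 16 bits over each channel's observed range and
  drops trailing samples beyond whole 1 s records; CSV output prints
  `%.17g`, which round-trips doubles exactly.

# Known limitations

- The generator's independence assumptions (between channels and between
  the background and components) are stronger than real EEG; no claim
  about clinical accuracy follows from the synthetic results.
- Subject-level generalization at 20 subjects is intrinsically
  high-variance; single-split accuracies can move by one test subject
  (~25 percentage points of a 4-subject partition) across seeds.
- The no-LSTM ablation is informative only when the class effect has
  spatial structure along the electrode axis (see above).
- Training is single-threaded R; the default widths are sized for minutes
  of CPU time, not for architecture search.
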