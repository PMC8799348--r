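---
title: "Feature-fusion capsule networks for sEMG gesture recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-fusion capsule networks for sEMG gesture recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fficaps)
```

## The classification problem

Surface electromyography (sEMG) records the electrical activity of
contracting muscle on the skin. A ring of 16 electrodes around the forearm,
sampled at 1000 Hz and band-limited to 20–500 Hz, carries enough information
to distinguish hand gestures — here five: hand closed (HC), hand open (HO),
radial flexion (RF), wrist extension (WE) and wrist flexion (WF). Two
practical difficulties dominate: the armband never sits in exactly the same
place twice (electrode displacement), and signal amplitudes differ strongly
between people.

`fficaps` classifies fixed-length signal windows with a capsule network fed
by a *feature fusion* front-end: classical per-channel signal features and
the raw signal segments are combined into a single two-dimensional input so
the network sees both domain-knowledge summaries and the waveform itself.

## Windowing

A continuous recording is cut into overlapping windows of `w = 300` samples
advanced by `tau = 50` samples (`slide_windows()`). Offsets are 0-based and
half-open; a trailing remainder shorter than `w` is dropped. Each window is
the unit of classification and inherits the recording's single gesture
label.

For the signal branch every window channel is cut into `n` segments of
length `l`, where `(n, l)` is the factor pair of `w` minimising `|n - l|`
(`solve_segmentation()`); mirrored pairs tie-break toward `n <= l`, so
`w = 300` gives a 15 x 20 segment matrix. The tie-break matters only for
perfect squares' neighbours; it keeps the matrix wider than tall, matching
the fixed 3 x 8 kernel geometry below.

## Per-channel features

Fourteen features per channel summarise each window
(`build_feature_vector()`), in fixed order: RMS, MAV, WL, ZC, DASDV, LOG,
SSI, TM3, TM4, TM5, FR, IEMG, MFMN, MFMD. Conventions worth noting:

* **ZC** counts sign changes `S_i * S_{i+1} < 0` whose step magnitude is at
  least a threshold `epsilon`; `epsilon` defaults to 0 because band-passed
  sEMG has negligible DC offset. The product is required to be strictly
  negative, so an exactly-zero sample does not count twice.
* **LOG** is evaluated literally as `exp(mean(S))`. The conventional LOG
  detector `exp(mean(log|S|))` is available behind `log_conventional =
  TRUE`; the literal form is the default for fidelity to the feature table
  this implementation follows.
* **Frequency-domain features** use the one-sided squared-magnitude DFT
  spectrum. MFMN is the power-weighted mean frequency; MFMD is the
  frequency at which cumulative power first reaches half the total (the
  conventional median frequency). The frequency ratio FR integrates power
  over a low band (default 20–250 Hz) and a high band (default 250–500 Hz)
  — a symmetric split of the 20–500 Hz device pass-band, configurable in
  `spectral_config()` — as discrete sums over bins whose centre lies in
  `[low, high)`.
* **Degenerate inputs**: an all-zero spectrum defines MFMN = MFMD = 0, and
  FR returns `NaN` with a warning rather than dividing by zero.

The feature vector is `f = (1, x1, ..., x14)`: the fixed leading 1 keeps
the original features present in the first row and column of the
outer-product map below.

## Feature fusion

Each channel contributes two matrices:

* the **feature map** `F = sigmoid(alpha * beta * f f^T)` with
  `alpha = beta = 0.5`, a symmetric 15 x 15 image of pairwise feature
  products squashed into (0, 1). The scalar product `alpha * beta` is read
  as one conversion factor 0.25 applied to the outer product before the
  sigmoid — the only parse in which both parameters act symmetrically on
  the two copies of `f`;
* the **segment matrix**, the 15 x 20 stacking of the raw window.

Both matrices are Min-Max normalised to [0, 1] *per channel* before the
learned layers (a constant matrix maps to zeros). Normalising raw input
matrices — rather than any learned convolution output — is the only
placement that is well-defined before training starts. Per-channel
normalisation discards absolute amplitude within each matrix; amplitude
information survives through the saturation pattern of the sigmoid feature
map, which differs between strongly and weakly active channels.

The 16 electrode channels enter as the depth dimension of both branches.
The front-end (`fusion_frontend()`) applies 256 stride-2 valid convolutions
with 3 x 8 kernels to the segment array and 256 with 3 x 3 kernels to the
feature array — both yield 7 x 7 maps, since `floor((15-3)/2)+1 =
floor((20-8)/2)+1 = 7` — concatenates them along channels (512) and mixes
with a 1 x 1 convolution back to 256 channels. Valid (unpadded)
convolutions are forced by this shape arithmetic.

## The capsule network

The 7 x 7 x 256 map passes through a **multilevel convolution block**
(`multilevel_conv()`): padded stride-1 3 x 3 and 5 x 5 convolutions (256
channels each) are concatenated with the block input (768 channels) and
reduced by a 1 x 1 bottleneck back to 256, aggregating multi-scale context
without pooling. Each learned convolution is followed by a ReLU; the
literature this architecture belongs to is silent on the conv
nonlinearity, and ReLU is the standard choice for capsule-network stems.

The output is reshaped into **primary capsules**: channels are grouped
into 8-dimensional vectors, giving `7 * 7 * 32 = 1568` capsules, each
squashed so its length lies in [0, 1) and can be read as an existence
probability.

**Dynamic routing** (`dynamic_routing()`) connects the 1568 primary
capsules to 5 action capsules of dimension 16. Prediction vectors are
`u_hat_ij = W_ij u_i` with per-pair 8 x 16 transform matrices. Routing
logits start at zero on every forward pass (they are not persisted across
batches); each of the 3 iterations computes coupling coefficients
`c_ij = softmax_j(b_ij)` (rows sum to 1; uniform 0.2 at initialisation),
weighted sums `s_j = sum_i c_ij u_hat_ij`, squashed outputs `v_j`, and the
agreement update `b_ij += u_hat_ij . v_j`. The update after the final
iteration would be dead computation and is skipped; gradients flow through
the full unrolled recurrence, couplings included.

### Squash family

`apply_squash()` implements five length maps `g(x)` (direction always
preserved; `g(0) = 0`):

| kind | `g(x)` |
|---|---|
| `squash` | `x^2 / (1 + x^2)` |
| `hsquash` | `(x/4)^2 / (1 + (x/4)^2)` |
| `strict_squash` | `0.69 x^2 2^(-0.6x - 1.115)` |
| `squash_4` | `x^2 / (0.5 + x^2)` |
| `e_squash` | `1 - exp(-x^2)` |

`e_squash` dominates the original squash for every length
(`(1+x^2)(1-e^(-x^2)) >= x^2`), so it responds more sharply once a capsule
starts to activate — the property motivating its use here. The selected
kind is used both for primary-capsule squashing and inside routing.
`strict_squash` is printed in its source as a scalar length formula; it is
implemented as that length times the unit direction vector, the only
reading that returns a vector. It is also the only kind not strictly
bounded by 1 (its maximum is about 0.997).

Numerical guard: directions are computed with `max(||s||, 1e-12)`; an
exactly zero vector maps to an exactly zero vector, with zero gradient.

### Loss and prediction

Each action capsule incurs a margin loss
`T_k max(0, m+ - ||v_k||)^2 + lambda (1 - T_k) max(0, ||v_k|| - m-)^2`
with `m+ = 0.9`, `m- = 0.1`, `lambda = 0.5`, summed over capsules and
averaged over the batch. Prediction takes the longest action capsule, ties
broken toward the lowest index for determinism.

## Implementation and training

The whole network — both forward and reverse passes — is implemented in
base R matrix algebra. Convolutions use precomputed im2col gather indices
so that each layer is a single matrix multiplication; the backward pass
scatters gradients through the same index plan. Dynamic routing is
vectorised across the batch with grouped row sums and validated against a
literal triple-loop implementation of the routing equations; every analytic
gradient is validated against central finite differences (relative error
below 1e-3, typically ~1e-5).

Training (`fficaps()`) uses Adam (learning rate 1e-3 by default, a
standard choice where the protocol specifies only the optimiser family),
minibatches of 32 (displacement protocol) or 16 (cross-subject protocol),
and a default budget of 30 epochs with no early stopping, favouring
reproducibility over speed. Weight initialisation is variance-scaled for
convolutions and N(0, 0.05^2) for the capsule transform matrices; all
randomness (init, shuffling) derives from one integer seed, so runs are
bit-reproducible per seed on a fixed platform.

Channel widths are configurable: the `"paper"` profile uses the full
256-channel layers; the `"test"` profile (32 channels, 196 primary
capsules) trains in a few minutes on one CPU and is used by the package's
own experiments; `"tiny"` (8 channels) serves gradient checks. Width only
scales capacity — the geometry (7 x 7 grid, capsule dimensions, 5 action
capsules) is identical across profiles.

## The synthetic data generator

The recordings this method was designed for are not publicly available, so
`generate_experiment()` produces synthetic datasets that reproduce the
*structure* the method assumes, with every choice documented here:

* **Gesture templates** (`make_templates()`): each gesture is a smooth
  activation bump (width ~4 channels) centred on a distinct location of
  the 16-channel ring over a 0.15 baseline, with small seeded jitter so no
  two envelopes coincide; `separation` (default 1) scales the bump height
  and hence between-gesture distance.
* **Signals** (`synthesize_window()`): per channel, envelope amplitude
  times band-limited (20–500 Hz) Gaussian noise plus additive white
  measurement noise (`noise_sd`, default 0.1). Band-limiting is exact
  spectral masking of white noise — no filter-design choices.
* **Subjects** (`subject_profile()`): per-channel multiplicative gains
  drawn log-normally (sigma 0.2), modelling electrode/skin impedance
  variability.
* **Electrode displacement**: a circular rotation of the channel ring by
  `shift` electrodes (default 1 in the displacement scenario), the natural
  geometry of an armband re-worn in a rotated position. Train windows use
  shift 0; test windows the shifted profile of the same subject.
* **Cross-subject scenario**: train subjects are disjoint from the single
  held-out test subject.
* Classes are exactly balanced; the default experiment size is 120
  training and 40 test windows per class (600/200 total), chosen so a full
  seeded replicate trains in about two minutes at the `"test"` width.

What the generator deliberately does **not** emulate: motor-unit action
potentials, muscle fatigue, inter-gesture transitions, nonstationarity
within a window, or realistic cross-talk spectra — all channels share the
same band-limited noise character and differ only in amplitude pattern.
Consequently, passing experiments on synthetic data demonstrate that the
pipeline can learn and retain gesture-specific spatial amplitude patterns
under displacement and gain variability; they do not certify accuracy on
real recordings, where class information is spread across waveform shape
as well as amplitude and published accuracies are materially lower.

## Replicates and reporting

`run_experiment()` reports accuracies as mean ± standard deviation over
independently seeded replicates (data generation, initialisation and
shuffling all re-seeded), the package's stand-in for the ± entries of the
usual results tables, whose replicate definition is not fixed by the
protocols it mirrors. `ablate_squash()` repeats the experiment across all
five squash kinds. The experiments the package's own tests run use the
`"test"` width profile, 3 replicates and the default dataset size — small
enough to re-run routinely, large enough that chance accuracy (20%) is
over thirty standard errors away.

## Known limitations

* The per-channel Min-Max normalisation choice (see above) is one of two
  defensible readings of the normalisation step; the alternative
  (normalising after the 1 x 1 mix) is not well-defined before training.
* `strict_squash` is implemented with a unit-direction factor its printed
  form omits.
* Training is CPU-bound base R; the full 256-channel profile is provided
  for structural fidelity and shape checks rather than routine training.
* The routing-iteration count (3) follows the source protocol; the
  implementation accepts any count >= 1 but skips the dead final update.
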