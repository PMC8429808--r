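---
title: "Subject-identification features for resting-state fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-identification features for resting-state fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea

A single 3D volume of a resting-state fMRI scan carries enough spatial
information to tell *who* is being scanned. `fmrisid` exploits this as a
self-supervised pretext task: a 3D convolutional network is trained to
classify the owning subject from one timepoint at a time, using softmax
cross-entropy against the one-hot subject identity. No diagnostic labels
enter the training; the teacher signal comes from the data itself. The
dense-layer outputs of the trained network then serve as general-purpose
per-timepoint feature vectors, and their per-subject temporal mean — the
**identity feature** — is the subject-level representation used downstream.

The package implements the full experimental chain on three disjoint
subject groups:

1. **train1** — trains the encoder (subject classification);
2. **train2** — fits linear models (diagnosis, age) on identity features;
3. **test** — evaluates those models on unseen subjects.

Splits are produced by `stratified_split()`, which fixes the per-split
patient/control counts exactly and deals subjects out of sex-by-age-tertile
cells so that sex and age are balanced across splits in expectation.
Continuous age cannot be stratified exactly; the tertile-cell scheme is the
package's choice of a reproducible approximation, randomised only within
cells under the given seed and invariant to input row order (rows are
canonically sorted by subject id first).

## Encoder architecture

`encoder_config()` describes the network: `n_blocks` blocks of two 3x3x3
convolutions (stride 1) followed by 2x2x2 average pooling, then
`n_tail_convs` convolutions at constant width, a flattening step and one
dense layer with a unit per training subject. Channel width starts at
`base_channels` after the first convolution and doubles once per block. At
the reference scale — input `(80, 96, 80)`, 4 blocks, base width 8 — the
width before the dense layer is 128 and the spatial map is `(5, 6, 5)`.

Choices the architecture description leaves open, and how they are fixed
here:

* **Padding.** A `(80, 96, 80)` input can only pass four halvings with the
  stated kernel/stride if convolutions preserve spatial size, so all
  convolutions use symmetric zero padding of 1.
* **Channel doubling position.** "Doubled before the pooling layer" is read
  as the second convolution of each block performing the doubling
  (`conv c -> c`, `conv c -> 2c`, `pool`); doubling at block entry is
  available as `double_at = "block_entry"`.
* **Dense input.** The dense layer is applied to the flattened feature map
  by default; a `dense_input = "global_pool"` variant applies it to
  channelwise spatial means instead. The two variants differ in parameter
  count (about 3.3M vs 1.3M at the reference scale), and
  `build_encoder()` reports the exact count for whichever is configured
  rather than asserting either number.
* **Nonlinearity.** ReLU after every convolution — the standard choice for
  this class of encoder. No batch normalisation, dropout or augmentation.
* **Initialisation.** Fan-in-scaled Gaussian weights, seeded through R's
  RNG; the dense layer starts at zero so an untrained network outputs the
  uniform distribution over subjects.

Training (`train_encoder()`) samples each minibatch uniformly with
replacement over all (subject, timepoint) pairs and optimises with Adam
under a staged learning-rate schedule (`train_config()`; the default
schedule mirrors the reference setting of 1e-4 followed by 1e-5). Input
intensities are standardised with a scalar mean and SD computed over the
training set and stored in the model, so optimisation is insensitive to
the arbitrary signal units of the scans; at unit input scale the 1e-4
rate is stable where substantially larger rates can drive the ReLU
network into a dead, chance-level state. The
training loop, forward pass and backpropagation are implemented in C++
(single precision, im2col plus cache-tiled matrix kernels) because no deep
learning framework is assumed; training is deterministic given the seed.
A non-finite loss aborts with a diagnostic rather than silently diverging.

## Features, identity features and precision@k

`extract_features()` evaluates the dense layer per timepoint
(*classification* variant). `center_features()` subtracts each vector's
element mean (*classification+*): the softmax is invariant to this shift,
so class probabilities are untouched while the feature geometry changes.
`identity_features()` averages vectors per subject.

`precision_at_k()` measures how tightly each subject's timepoints cluster
around their identity feature: all feature vectors of all subjects are
pooled, ranked by Euclidean distance to the identity feature in the
original (unstandardised) feature space, and precision@k is the fraction of
the k nearest that belong to that subject; the per-subject values are then
averaged. Three deterministic conventions: the identity feature itself is a
centroid and never part of the ranked pool; ties break by (distance,
subject id, timepoint); and k defaults to the per-subject timepoint count
(150 at the reference scan length), since then a perfectly clustered
subject scores exactly 1.

## Baselines

Three comparison feature sets flow through the *same* identity-feature and
precision code paths:

* **ROI pooling** — `pool_rois()` averages voxels within each region of an
  integer atlas; each timepoint's region-mean vector is its feature. Empty
  regions (possible after cropping) are dropped with a warning rather than
  zero-filled, so connectivity matrices never contain constant columns.
* **PCA** — `fit_pca()`/`project_pca()`: mean-centred principal components
  of the train1 timepoints-by-voxels matrix, fitted once on train1 only
  (mirroring how the encoder sees only train1) and applied to all splits.
  Desk-scale work uses small m; the exact SVD route is adequate there.
* **Functional connectivity** — `connectivity()`: the Pearson correlation
  matrix among ROI time series over the full scan (static connectivity, no
  windowing); the vectorised upper triangle is the subject's feature.

## Downstream evaluation

`fit_diagnosis()` is a logistic-loss linear classifier. With D features and
a handful of train2 subjects the problem is underdetermined, so an L2
penalty with a fixed default strength (`lambda = 0.1`) is applied;
`lambda` is exposed because accuracy in the p >> n regime is sensitive to
it. Classification thresholds the linear score at zero, with exact ties
assigned to the control class. `fit_age()` is ridge-penalised least squares
in closed form, so `lambda = 0` reduces exactly to ordinary least squares.

Significance: `sign_test()` is the exact one-sided binomial tail
`P(X >= n_correct | n, 1/2)` — one-sided because the question is whether
accuracy exceeds chance. `pearson_test()` uses the t transform with a
two-sided p-value, the conservative default where sidedness is not
dictated.

## The synthetic cohort generator

Real multi-subject fMRI is not required anywhere. `simulate_scan()` builds

```
v(x, t) = B(x) + a_sig * S_i(x) + a_grp * G(x) * 1(patient)
        + a_age * A(x) * z(age_i) + eps(x, t)
```

with `B` a smooth ellipsoidal "brain" baseline, `S_i` a per-subject
Gaussian random field smoothed by a configurable kernel (spatially
structured, like fMRI, rather than white noise), `G`/`A` fixed smooth
effect maps, `z` the standardised age, and `eps` i.i.d. Gaussian temporal
noise. The subject signature is **constant over time**: that is precisely
the premise that makes single-timepoint identification possible, and it is
the property the encoder is supposed to discover. Fields are keyed by
(seed, subject id), so the same subject keeps their signature across scans
and sessions while different subjects get independent fields; datasets are
bit-reproducible under a fixed seed.

What the generator deliberately omits: hemodynamics, physiological noise,
scanner drift, temporal autocorrelation, anatomy, and any realistic
between-region correlation structure. Passing tests on this generator
therefore demonstrate that the machinery — architecture, optimisation,
feature construction, metrics, statistics — behaves as specified when the
assumed signal structure is present; they say nothing about effect sizes on
real cohorts.

## Desk-scale study conditions

The bundled `desk.yaml` fixes the package's reference synthetic experiment,
sized for a single CPU:

* 34 subjects (17 patients, 17 controls), split 12 / 8 / 14 into
  train1 / train2 / test; 40 timepoints each on a 24 x 28 x 24 grid;
* signature amplitude 5 and group-effect amplitude 4 in noise-SD units —
  strong effects by design: the desk run verifies mechanism, not realistic
  effect sizes, and needs both stages (identification and group
  discrimination) to carry signal at small n;
* a 2-block encoder (base width 8), trained for 2,000 Adam iterations
  (1,500 at 1e-4, 500 at 1e-5 — the reference two-stage schedule, shortened
  to match the much smaller problem) with minibatches of 4 single
  timepoints, which converge well past the 90% training-accuracy mark at
  this problem size;
* precision evaluated at k = 40, the per-subject timepoint count;
* baselines: a 12-parcel synthetic atlas (k-means on voxel coordinates
  inside the brain mask), 3 principal components, connectivity, and a
  pure-noise feature control.

The type-I-error study uses 100 independent null cohorts (no group effect)
at a further reduced size (8-cubed grid, ROI features, 8 train2 and 18 test
subjects) so that the whole study stays inexpensive while the sign test is
exercised end to end at the reference test-set size of 18.

## Numerical notes and limitations

* Network arithmetic is single precision; feature extraction is
  deterministic, and equality-sensitive tests compare at 1e-5 or looser.
  Statistics (sign test, correlations, PCA) are double precision.
* The spec of the reference network's "about 2 million" parameters is not
  exactly reproducible from its textual description: the flatten variant
  counts about 3.3M and the global-pool variant about 1.3M. The package
  reports computed counts and exposes both variants.
* The crop window that maps a 91 x 109 x 91 grid to (80, 96, 80) is not
  uniquely determined by "trimming outside the brain"; `crop_volume()`
  defaults to a centre crop, accepts an explicit offset, and records the
  window used in the volume's provenance.
* `stratified_split()` balances age in expectation only; exact age
  stratification is impossible with continuous ages.
* Distances for precision@k are computed in the raw feature space; no
  standardisation is applied, so the metric is not invariant to per-feature
  rescaling (it is invariant to common translations).
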