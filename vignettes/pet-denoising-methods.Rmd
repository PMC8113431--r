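---
title: "Methods: phantom simulation, network training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom simulation, network training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(petdenoise)
```

## The problem

Whole-body FDG PET images are count-starved: at a fixed injected activity
(4 MBq/kg), the image noise level is governed by the acquisition time per
bed position. Clinics would like to scan faster (1 min/bed instead of the
standard 1.5 min) without losing diagnostic image quality, and without
biasing the quantitative uptake measures (SUVmax, SUVpeak) that drive
staging and response assessment.

`petdenoise` implements a post-reconstruction enhancement approach: a 3D
convolutional denoising network is trained on pairs of *short-time* (noisy)
and *long-time* (clean) reconstructions derived from a single acquisition by
time-splitting, then applied to whole volumes. Because no public PET raw
data accompany the approach, the package also ships a synthetic phantom
module that emulates the acquisition design end to end, plus the full
quantitative and statistical evaluation battery (liver COV noise protocol,
lesion SUVmax/SUVpeak, Bland-Altman agreement, Friedman/Wilcoxon and
Kruskal-Wallis/Mann-Whitney suites with Bonferroni bookkeeping).

## The phantom and acquisition emulation

A phantom is a uniform soft-tissue background (default SUV 0.7), an
ellipsoidal liver compartment (SUV 2.0), and three spherical hotspots per
subject with true SUV drawn uniformly in [2, 8] and diameters in
[10, 25] mm — small-to-middle-sized lesions spanning a wide SUV range. The
default grid is 71 slices of 128 x 128 voxels at 2.7 x 2.7 x 2.8 mm; the
clinical 256 matrix is supported but the 128 grid keeps a desk-scale run in
minutes. Background and liver levels are conventional whole-body FDG values
(soft tissue well below liver; liver ~2 SUV).

Acquisition is emulated statistically rather than event-by-event:

* `simulate_frame()` draws independent Poisson counts per voxel with mean
  `activity x duration x sensitivity`. The scanner sensitivity is a free
  parameter: no absolute count calibration is available. Its default (1.5
  counts per SUV-unit per minute per voxel) was set once so the emulated
  1-min image set shows a liver COV of roughly 10% after reconstruction —
  the order of magnitude reported for short-acquisition clinical FDG
  studies. Only noise *orderings* across durations are meaningful, not
  absolute magnitudes.
* `split_frame()` emulates list-mode sub-interval reconstruction by exact
  multinomial thinning: the sub-frames sum voxelwise to the parent frame.
  Sub-frames of one parent are therefore negatively correlated at fixed
  total — exactly as sub-intervals of one real acquisition are. The
  training design derives the four 1.5-min quarters and the first four
  1-min sixths from one 6-min frame; the test design thins a 4-min frame to
  1.5 and 1 min (`subframe()`).
* `emulate_reconstruction()` stands in for a penalized iterative (BSREM-type)
  reconstruction. The regularization strength beta maps monotonically to an
  additional Gaussian FWHM (default `2 + beta/250` mm) combined in
  quadrature with a 4-mm intrinsic PSF. Only the qualitative beta -> noise
  trade-off matters for exercising the method; the commercial algorithm
  itself is out of scope. Smoothing uses half-sample symmetric boundaries
  with a normalized kernel, so constants are fixed points and the voxel sum
  is conserved exactly.
* SUV scaling uses the universal convention
  `SUV = concentration [kBq/mL] x weight [kg] / injected [MBq]` with 1 g/mL
  tissue density and no decay correction — all comparisons are
  within-subject at a single time point, so decay cancels.

What the phantom does *not* emulate: attenuation, scatter, randoms,
time-of-flight, detector geometry, respiratory motion, and anatomical
texture. Passing tests therefore demonstrate that the method behaves as
designed under Poisson counting statistics and a resolution/noise trade-off;
they do not certify performance on patient data.

## Training data

Training follows the acquisition design exactly: each training subject
contributes one clean 6-min reconstruction (beta 200) and four short
reconstructions (beta 500). Volumes are cropped to the 50 centremost slices
(`crop_central()`; when the discard count is odd, one extra slice is dropped
at the end — a fixed convention, since "centremost" does not determine the
split), then partitioned into ten contiguous 5-slice blocks
(`partition_subsets()`).

Augmentation is geometric and strictly in-plane: a uniform scale in
[0.9, 1.1], a shear in [-0.1, 0.1], and independent flips with probability
0.5, resampled bilinearly. The magnitudes are mild, consistent with
"randomly resized, sheared and flipped", and are configurable. The *same*
transform is applied to a noisy volume and its clean counterpart — an
untransformed target would make the pair spatially inconsistent.

The pair count obeys
`subsets x sources x reconstructions x (1 + augmentations)`; with the full
design of 72 subjects, 4 reconstructions and 5 augmented samples this gives
10 x 72 x 4 x 6 = 17,280 pairs per network. Two networks are always trained
from separate pair sets built by the same code path: one for 1-min inputs,
one for 1.5-min inputs.

## The network

`cnn_build()` constructs a plain 3D convolutional stack in the
residual-learning denoising lineage: by default 10 same-padded 3x3x3
convolution layers, 68 filters in the hidden layers, batch normalization on
the hidden layers, a rectifier after every layer except the last, and no
pooling (to preserve the receptive field). The first layer takes the single
input channel; the last returns a single channel. We read the single-filter
wording for the outer layers as single *channels* — a literal one-filter
first layer would collapse the network's capacity, and the architecture
family this design follows uses 1-channel ends.

Open design points, decided as follows:

* **Residual mode (default on).** The network predicts the noise map, which
  is subtracted from the input. This is the convention of the architecture
  lineage and trains faster at shallow depth; direct prediction of the
  clean image is a config switch.
* **Normalization.** Blocks are divided by a single global constant (the
  training set's 99.5th intensity percentile) and multiplied back after
  inference, so the network is unit-preserving in SUV. In residual mode the
  training target (noisy minus clean) is additionally standardized to unit
  variance — the standard noise-level normalization of this architecture
  family. Without it the loss surface is so flat at realistic PET noise
  levels that plain SGD converges to the identity mapping; the
  standardization is inverted at inference, so predictions are still in
  SUV.
* **Optimizer.** Mean-squared-error loss with SGD + momentum 0.9. Learning
  rate, batch size and epochs are unreported upstream; the package defaults
  are 1e-3 / 8 / 20 in `cnn_config()`, and the desk-scale pipeline config
  uses 0.01 / 4 / 12 (see below).
* **Whole-volume inference.** `denoise_volume()` slides the 5-slice window
  with stride 1 and averages overlapping predictions per slice; how 5-slice
  outputs should tile a 71-slice body is unspecified upstream, and stride-1
  averaging is the variance-minimizing choice.
* **Batch norm at inference** uses frozen running statistics (momentum 0.1),
  so inference is deterministic and independent of batch composition.

## Desk-scale study conditions

The full 10 x 68 architecture on 256 x 256 x 5 blocks is far beyond a
single-CPU desk run, so the end-to-end pipeline (`run_config()`,
`run_study()`) fixes a compact but structurally identical configuration,
chosen once as the package's study conditions:

* training phantoms on a 64 x 64 x 71 grid, so training blocks are natively
  64 x 64 x 5;
* 3 training subjects x 4 reconstructions x 10 subsets x (1 original + 1
  augmented sample) = 240 pairs per network;
* networks with 4 layers x 8 filters (receptive field 9 x 9 x 9, ample for
  noise correlated over ~1 voxel), trained 12 epochs with learning rate
  0.01, batch size 4;
* 10 test subjects on the default 128 x 128 x 71 grid, evaluated on all
  five image sets (4 min at beta 300; 1.5 min and 1 min at beta 500, each
  with and without enhancement).

These sizes train a network in a few minutes on one CPU while leaving the
architecture, loss, optimizer, pairing design and evaluation protocol
identical to the full-scale configuration.

## Quantification and noise metrics

* `suv_max()` is the maximum voxel in the lesion VOI; `suv_peak()` is the
  maximal mean over a 1-cm3 sphere (radius 6.2 mm, voxel-centre
  rasterization; the rasterized volume is within one voxel of 1 cm3 at the
  default voxel size). The sphere is centred to maximize the sphere mean
  within the VOI (harmonization-style convention); centring on the SUVmax
  voxel is a config option. By construction `suv_peak <= suv_max`.
* `cov_liver()` implements the liver noise protocol: three 6-cm circles on
  transaxial slices i, i+2, i+4, drawn once per subject (on the phantom's
  liver centroid) and copied unchanged to all five image sets. Per circle,
  COV = population SD / mean; the three values are averaged. Whether the
  upstream protocol used population or sample SD is unreported; population
  SD is the default and the choice is configurable. COV is scale-invariant,
  so the choice of SUV normalization cannot affect it.
* `bland_altman()` reports mean difference, sample-SD-based 95% limits of
  agreement, the trend of difference on pairwise mean, and t-based
  confidence limits for the mean difference and each limit (standard error
  `sd * sqrt(1/n + z^2/(2(n-1)))`). The "exact" CI method referenced in the
  source material is unidentified; the t-based interval is used and labelled
  as such.

## Statistics

The comparison suite mirrors the standard reporting layout: per metric
(SUVpeak, SUVmax, COV) a Friedman omnibus over the five related image sets,
then all C(5,2) = 10 pairwise Wilcoxon signed-rank tests at the Bonferroni
threshold 0.05/10 = 0.005; for reader scores, Kruskal-Wallis omnibus per
reader/category then 10 pairwise Mann-Whitney tests at the same threshold.

The paired Wilcoxon test is implemented in-package because the contract —
an exact two-sided null for up to 25 retained pairs *with mid-rank ties* —
is not available in base R (which refuses exact p-values under ties). The
exact null is built by a generating-function recursion over doubled ranks;
zero differences are dropped; beyond 25 pairs a normal approximation with
continuity and tie corrections takes over. The two-sided p doubles the
smaller tail and is capped at 1. Friedman, Kruskal-Wallis (tie-corrected H)
and Mann-Whitney (exact when the smaller sample has <= 8 observations and no
ties; tie-corrected normal approximation otherwise) delegate to the standard
base-R implementations behind the package's uniform tidy interface. All
tests are two-sided. Tests are validated against exhaustive
enumeration/permutation oracles in the test suite; the chi-square omnibus
approximations are documented as accurate only to about +/-0.1 in p at the
tiny table sizes the oracles can enumerate.

## Numerical choices and degenerate inputs

* Multinomial splitting uses sequential binomials (exact), so count
  conservation is bitwise.
* Convolutions run in single precision by default (mixed-precision
  training, standard for this model family): float32 gives about twice the
  BLAS throughput and is far more accurate than the SGD noise floor; a
  double-precision path remains available (`precision = "double"`) and is
  used for the finite-difference gradient verification in the test suite.
* Gaussian smoothing truncates the kernel at 4 sigma and normalizes it.
* A circle ROI with non-positive mean and a VOI outside the volume raise
  errors rather than returning NaN; an all-zero-difference Wilcoxon input
  returns a flagged degenerate result with p = 1.
* All stochastic operations are pure functions of (inputs, seed); the
  pipeline derives per-stage seeds from one master seed and records them.

## Known limitations

* Absolute noise levels depend on the uncalibrated sensitivity surrogate;
  only orderings across durations/image sets are meaningful.
* The reconstruction surrogate cannot reproduce resolution recovery or
  convergence artefacts of penalized iterative algorithms.
* The reader study cannot be reproduced computationally; the bundled reader
  score summary table supports the ranking/reporting operations, and an
  automated lesion-preservation check on phantom ground truth
  (`check_lesion_preservation()`) stands in for the side-by-side hotspot
  review.
* Training-set sub-frames derived from one parent frame share events with
  each other (negative correlation at fixed total); this mirrors the actual
  design and is accepted rather than corrected.
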