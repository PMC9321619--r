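---
title: "Methods: multitask Siamese estimation of heart and respiration rates from facial video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitask Siamese estimation of heart and respiration rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(siamvitals)
```

## The estimation problem

A camera pointed at a face records two weak physiological signals. The
cardiac signal (remote photoplethysmography, rPPG) appears as a periodic
skin-colour modulation, strongest in the green channel, driven by
blood-volume changes in facial vessels; its fundamental lies in the cardiac
band 0.66–3.3 Hz (≈ 40–198 beats per minute). The respiratory signal appears
as slower intensity and motion changes in the respiratory band 0.1–0.4 Hz
(6–24 respirations per minute). `siamvitals` regresses both per-frame traces
simultaneously from two facial regions and converts each trace to a rate via
filtering and peak-interval analysis.

## Network

Two regions of interest — forehead and cheek — are standardised to
140 (w) × 40 (h) × 3 clips of T frames with values in [0, 1] and fed to two
branches of one convolutional network. The branches **share a single
parameter set**: sharing is structural (both branches literally traverse the
same arrays), so it cannot drift apart during optimisation, and shared
parameters are counted once.

Each branch stage applies, per frame:

1. a 3×3 same-padded convolution with leaky-ReLU activation
   (`LeakyReLU(x) = x` for `x ≥ 0`, `0.01·x` otherwise; the slope 0.01 keeps
   a small gradient on the negative side so units cannot knock out);
2. a 1×1 convolution that reduces the channel count — the main lever that
   keeps the parameter total below a megaparameter;
3. a convolutional block attention module (CBAM): channel attention
   (average- and max-pooled channel descriptors through a shared two-layer
   ReLU bottleneck with reduction ratio 8, summed, sigmoid) followed by
   spatial attention (channel-wise mean and max maps convolved with a 7×7
   kernel, sigmoid); every gate is strictly inside (0, 1);
4. 2×2 max pooling after the first two of the three stages.

A per-frame dense readout (flatten → 1 scalar, inside the branch and thus
shared) turns the stage-3 feature map of each frame into one sample; the two
branch traces are merged by **elementwise addition** into the T-sample PPG
output. Deliberately, no dense layer follows the addition on the PPG path.
In multitask mode the per-frame flattened features of the two branches are
added, passed through dropout, and mapped by one dense layer to the T-sample
respiration trace.

### Frozen default widths and the parameter budgets

The per-stage widths are frozen at `conv_filters = (32, 128, 500)` and
`reduce_filters = (16, 128, 86)`. With the 40×140 input pooled twice to
10×35, the final per-frame feature vector has 10·35·86 = 30 100 entries, so
each dense head costs 30 101 parameters. The totals are 722 892 trainable
parameters for the multitask network and 692 791 for the single-task variant
(multitask minus the respiration head), i.e. 0.72 M and 0.69 M — the
published budgets for the two variants. The widths were chosen once to land
on those budgets, which are the only hard printed constraints on the
architecture; the block structure (3×3 conv + 1×1 reduction + CBAM per
stage, two poolings, add-merge, dense respiration head) follows the
published block diagram.

### Design choices where the architecture was under-specified

* **Temporal handling.** Frames are the leading axis and convolutions are
  purely spatial; temporal structure enters only through the per-frame
  readout producing a T-sample trace whose *correlation* with the reference
  is optimised. This is the simplest reading consistent with a
  600-in/600-out interface; a temporal (3-D) convolution variant would
  change the parameter budget substantially.
* **Respiration head placement.** "A dense layer after the merge" cannot map
  the T-vector to a T-vector at the published budget (600·600 ≈ 0.36 M
  alone); the head therefore reads the *added per-frame feature vectors* and
  maps each frame to one sample (30 101 parameters ≈ exactly the 0.03 M gap
  between the two published totals). This is recorded as the package's
  interpretation.
* **Dropout rates** (0.25, 0.5, 0.6) are assigned shallow→deep: after the
  stage-2 pooling, before the PPG readout, before the respiration head. They
  are configurable; training-mode only (inverted dropout).
* **CBAM order** is channel-then-spatial, after each stage's activations,
  the order recommended by the module's authors.
* **Initialisation** is Glorot-uniform with a recorded seed and zero biases;
  with zero-initialised attention weights every gate would start at exactly
  0.5 (the sigmoid of zero), which the tests use as a fixed point.

## Losses and optimisation

Each task is trained with the negative-Pearson loss `1 − r(x, y)`, bounded
in [0, 2] and invariant under positive affine rescaling of either argument —
appropriate because camera-derived traces have no calibrated amplitude. The
multitask loss is the unweighted sum of the two task losses (weights
exposed in `train_config()`); no weighting scheme was published, so equal
weights are the default. A constant signal makes the correlation undefined;
the package returns r = 0 (loss 1) with a `degenerate` flag and a zero
gradient rather than dividing by zero, keeping training alive on
pathological batches.

Optimisation is Adam (learning rate 1e-4, β₁ = 0.9, β₂ = 0.999,
ε = 1e-8) with batch size one, i.e. one gradient step per clip over the full
T samples. The epoch budget of 250 is treated as an upper bound; the
checkpoint with the lowest validation total is retained (lowest training
total when no validation clips are supplied). Both the forward and backward
passes are implemented in the package (direct compiled convolution kernels,
analytic gradients for CBAM including the argmax routing of the max-pooled
descriptors, maxpool tie-breaks to the first candidate in raster order), and
the backward pass is verified against central finite differences in the test
suite.

## Rate extraction

Predicted and reference traces are treated identically. A trace of kind
`ppg` is bandpass-filtered with an order-4 Butterworth design at
0.66–3.3 Hz; a `respiration` trace with order 2 at 0.1–0.4 Hz. Filtering is
forward–backward (zero phase) so peak times are not shifted; the effective
magnitude response is therefore the *square* of the single-pass Butterworth
response, which the tests check against the analytic transfer function. Edge
transients are suppressed by odd-reflection padding of length three filter
lengths (capped at signal length − 1).

Peaks are local maxima with topographic prominence at least 0.3 times the
signal standard deviation and minimum separation `1/high_hz` seconds (taller
peaks win ties); these two constants are documented defaults, not published
values, and are overridable. Peaks near the trace edges are kept. The rate
is 60 divided by the mean inter-peak interval, algebraically
`60·(N−1)/(p_N − p_1)`. Agreement between predicted and reference rates is
summarised per clip set by Pearson R, MAE and RMSE; MAE ≤ RMSE holds for
every report by Jensen's inequality and is asserted in tests.

## Synthetic data generator

The generator emulates the data contract of a webcam vital-signs corpus —
20 FPS, 600-frame clips, 140×40 forehead and cheek ROI streams with paired
reference traces, 8-bit pixels — without shipping or depending on any
recordings:

* the cardiac truth is a fundamental sinusoid plus a 0.3-amplitude second
  harmonic, normalised to [−1, 1]; the harmonic gives an asymmetric,
  pulse-like shape so peak detection is exercised beyond a pure sine;
* the cardiac modulation enters pixel intensities predominantly through the
  green channel (relative channel weights 0.25/1/0.25; the cheek modulates
  slightly deeper than the forehead);
* respiration enters through two independently switchable mechanisms at the
  respiratory frequency: a global intensity modulation and a ≤ 1-pixel
  sinusoidal vertical translation of a fixed spatial texture — how
  respiration manifests in real facial video is not established, so this
  simulator is a stand-in, not a physiological claim;
* per-pixel Gaussian noise (default sd 2 of 255 levels) and a slow
  illumination drift (default 3 levels at 0.02 Hz) are superimposed, and
  pixels are quantised to 8 bits with clipping, matching consumer-camera
  output.

Default modulation depths (2 % of the intensity scale) are strong relative
to real rPPG but appropriate for a correctness-oriented simulator: after
spatial averaging over thousands of pixels the per-pixel noise is negligible,
so recoverability failures indicate implementation errors, not bad luck.
Identical configuration and seed give bit-identical clips; the cardiac truth
is an analytic function of the cardiac frequency alone, so changing
respiratory parameters cannot perturb it.

What the generator does **not** emulate: photorealistic faces and landmark
jitter, skin-tone diversity, subject motion, compression artefacts, lighting
changes with spectral structure, or the empirically unknown coupling between
respiration and facial appearance. Passing the end-to-end tests therefore
demonstrates that the pipeline is implemented correctly and can learn the
embedded signals, not that the published accuracy transfers to real
recordings — reproducing those numbers requires the gated benchmark corpus
and is out of scope here.

## Problem sizes used in tests

The test suite trains a reduced model of the same architectural family:
T = 128 frames, 32×12 ROIs at 10 FPS, widths (8, 12, 16)/(4, 6, 8), 32
training clips, 8 held-out clips, 30 epochs with the default optimiser
settings. The 10 FPS rate was fixed a priori so the 12.8 s window holds at
least two respiration cycles across a realistic respiratory range (the
window constraint `n_frames ≥ 2·fps/rr`); heart frequencies are drawn
uniformly from 0.9–2.4 Hz and respiratory frequencies from the admissible
part of 0.1–0.4 Hz. At this size the held-out heart-rate MAE is essentially
zero and the respiration-rate MAE well under 1 RPM, and the entire
simulate→train→evaluate pipeline is bit-reproducible from its seed.

## Interfaces and limitations

* Landmark detection is out of scope: landmarks enter as 68-point frames
  (iBUG ordering) from CSV or any callable producing them; "top of the
  head" for the forehead box is the eyebrow line extended upward by 0.4×
  the eyebrow-to-chin distance, since 68-point sets contain no hairline
  point.
* Real-mode video enters as an in-memory `(T, H, W, C)` array, an `.rds`
  array file, or a directory of frame images; reference traces enter as CSV
  (`time`, `value`). Reference resampling is linear interpolation at the
  centred frame window.
* Intensities are standardised by a fixed affine map (division by 255 for
  8-bit input), keeping train and test consistent; resizing is bilinear
  with half-pixel centres.
* Full-size (600-frame, 140×40) *training* is memory- and compute-heavy in
  this implementation; the package trains the reduced family routinely and
  builds/serves the full-size network (parameter counting, prediction) but
  does not attempt to reproduce published benchmark accuracies, which were
  measured on a gated corpus.
* Metrics are computed per clip (one rate per clip), the natural reading of
  the evaluation protocol; windowed variants are not implemented.
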