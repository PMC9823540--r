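---
title: "Bi-CLSTM thrombus segmentation: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-CLSTM thrombus segmentation: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombseg)
```

## The clinical problem

After endovascular aneurysm repair (EVAR) of an abdominal aortic aneurysm,
the aneurysm sac is excluded from circulation by a stent graft and fills
with thrombus. Long-term surveillance relies on CT angiography (CTA):
clinicians track the thrombus volume to detect endoleaks and sac growth.
Manual delineation is slow, and automatic segmentation is hard for two
reasons visible in any postoperative CTA volume: the thrombus intensity
distribution overlaps that of the adjacent soft tissue, and the metallic
stent graft scatters bright streak artifacts across the region of interest.

A thrombus, however, is a three-dimensional structure: its cross-section
changes slowly from one axial slice to the next. `thrombseg` exploits this
*volumetric coherence*. Instead of segmenting each slice independently, it
feeds a short, ordered window of adjacent slices to a recurrent model that
integrates evidence along the axial direction in both directions.

## The model

For a target slice $x_t$, the method forms the sequence of $N$ pairs
$\{(x_{t+o}, a_{t+o})\}_{o=-h}^{h}$, $h = (N-1)/2$, where $a_s$ is the
*spatial attention map* of slice $s$: a per-pixel foreground probability in
$[0,1]$ produced by a detection-style backbone. $N = 5$ by default; windows
of 3 and 7 behave similarly, and positions beyond the volume ends are
filled by replicating the boundary slice. Each pair is stacked as a
2-channel image (intensity on the unit scale, attention map) and encoded by
two residual blocks

$$\mathrm{out} = \mathrm{ReLU}\bigl(\mathrm{project}(x) +
  \mathrm{BN}(\mathrm{Conv}(\mathrm{ReLU}(\mathrm{BN}(\mathrm{Conv}(x)))))\bigr),$$

with 64 filters each in the full configuration; `project` is a 1×1
convolution when the channel counts differ and the identity otherwise.

The encoded sequence is processed by a convolutional LSTM whose gate
transformations are 2D convolutions (128 filters by default):

$$
\begin{aligned}
i_t &= \sigma(W_{xi} * x_t + W_{hi} * H_{t-1} + w_{ci} \circ C_{t-1} + b_i)\\
f_t &= \sigma(W_{xf} * x_t + W_{hf} * H_{t-1} + w_{cf} \circ C_{t-1} + b_f)\\
C_t &= f_t \circ C_{t-1} + i_t \circ \tanh(W_{xg} * x_t + W_{hg} * H_{t-1} + b_g)\\
o_t &= \sigma(W_{xo} * x_t + W_{ho} * H_{t-1} + w_{co} \circ C_t + b_o)\\
H_t &= o_t \circ \tanh(C_t)
\end{aligned}
$$

Two such cells run over the window in opposite directions (axial volumes
have no privileged direction), their hidden maps are fused per position —
channel concatenation by default, elementwise sum as an alternative — and a
final convolution stack (a 64-filter fusion convolution, then a 1×1 logit
convolution and sigmoid) produces the per-pixel thrombus probability of the
target slice. The binary mask applies the configured threshold with a
`>=` comparison so exact ties are foreground.

Training minimizes the focal loss
$\mathrm{FL}(p_t) = -\alpha_t (1-p_t)^\gamma \log p_t$, which down-weights
the abundant easy background pixels; probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$ before the logarithm. Optimization is plain SGD.

All of this — convolutions, batch normalization, the ConvLSTM cell,
backpropagation through time, focal-loss gradients — is implemented
directly in R on top of BLAS matrix products (an im2col formulation). The
backward pass is exact: the test suite compares every layer group's
analytic gradient against central finite differences, and the cell against
a scalar LSTM oracle.

## The attention backbone

The reference design extracts attention maps from a Mask R-CNN-style
instance detector (ResNet-50 FPN backbone, RPN with three anchor scales and
three aspect ratios, RoI Align, 1024-neuron box/class heads) and consumes
only its mask branch. `detector_config()` captures exactly that
configuration surface and `configure_detector()` enforces its contract.
Because this package is pure R, the handle is backed by a compact fully
convolutional scoring network rather than a full detector: its thresholded
output is split into 8-connected candidate instances, each scored by its
peak probability and boxed by its tight rectangle, and only the
highest-scoring instance's soft mask is pasted into the full-image
attention map (ties broken by the lower index; no instance above the score
threshold yields an all-zero map, not an error). A second provider,
`lightweight_backbone()`, returns the dense per-pixel probability directly.
Both providers honor one output contract and are interchangeable
downstream; both train with the pixel-wise focal loss. The two-stage
reading of the pipeline is adopted: attention maps are precomputed (and
cached) before the head is trained, rather than training both jointly.

## Data handling

* **8-bit rescaling.** The full contrast range is mapped linearly to
  $[0, 255]$ with no window-level adjustment, rounding half to even.
  Per-volume min/max is the default; a fixed intensity range is available
  because the acquisition convention is not always knowable from the data.
  A constant volume maps to zeros rather than erroring, so degenerate
  synthetic cases cannot abort a pipeline.
* **Slice exclusion.** Slices whose ground-truth mask is empty are removed
  before training (`filter_slices_with_roi()`), keeping their original
  axial indices; a study with no ROI-bearing slice is an error.
* **Bounding boxes.** Detection-style ground truth is derived by fitting
  tight rectangles to masks, one per 8-connected component by default.
  Coordinates are 0-based `(row, col)`, inclusive at both ends — stated
  once here and enforced by tests, since conventions differ across tools.
* **Masks** are stored as `{0,1}` integers; every reader validates
  binarity.
* **IO.** NIfTI (via `RNifti`) is the primary on-disk dialect; a PNG stack
  with a JSON manifest serves as a lightweight fixture format. Integer
  payloads round trip bit-exactly in both.

## Augmentation

Two augmentations are provided: rotation within ±10° and elastic
deformation (uniform displacement noise smoothed by a Gaussian of
`elastic_sigma` pixels, scaled to `elastic_alpha` pixels; defaults 4 px and
8 px at 64×64, chosen to be visually mild and scale-proportional). One
transform is always sampled per call and applied identically to image and
mask — bilinear resampling for the image, nearest-neighbour for the mask so
it stays binary. When a whole sequence is augmented, a *single* transform
is shared by all N pairs: independent per-slice warps would destroy the
inter-slice coherence that the recurrent model exists to learn. Warping
attention maps alongside the images is the default in the two-stage
pipeline; recomputing them from warped images is possible when a backbone
is at hand but costs a forward pass per slice. Augmentation multiplicity is
on-the-fly: one fresh draw per training step, reseeded deterministically.

## Evaluation protocol

Five metrics compare a prediction $A$ against a nonempty ground truth $B$:

| metric | definition |
|---|---|
| total overlap | $|A \cap B| / |B|$ |
| false negative | $|B \setminus A| / |B|$ |
| false positive | $|A \setminus B| / |A|$ |
| Dice | $2|A \cap B| / (|A| + |B|)$ |
| Jaccard | $|A \cap B| / |A \cup B|$ |

Two identities follow: $TO + FN = 1$ (exactly, including in floating
point) and $\mathrm{Dice} = 2J/(1+J)$. The suite asserts both on a
thousand random mask pairs. An empty prediction is defined to give
$TO = \mathrm{Dice} = J = 0$, $FN = 1$ and $FP = 0$ (the $|A|$ denominator
is empty); the alternative convention $FP = |A \setminus B|/|B|$ is
available behind `fp_denominator = "gt"`, because published aggregates do
not pin the denominator down and both appear in the literature.

Cross-validation is patient-wise: studies, never slices, are shuffled once
and partitioned into $k$ test sets (default $k = 4$; 60 studies yield the
45/15 train/test rotation). Aggregation is the unweighted mean at each
level of the slice → study → fold → overall hierarchy, so large volumes do
not dominate cohort numbers.

## The synthetic phantom

Clinical postoperative CTA datasets are private, so the package ships a
deterministic phantom generator (`phantom_params()`, `generate_study()`,
`generate_cohort()`) that reproduces the properties the method is sensitive
to, on a 64×64 grid by default (256 for demos):

* a bright circular lumen (the stented channel);
* an annular thrombus around it — the ground-truth mask — with an irregular
  outer boundary built from low-frequency radial harmonics, rendered as a
  single 8-connected component per slice;
* a soft-tissue field whose intensity distribution overlaps the thrombus
  distribution by a controllable fraction (`tissue_overlap`): both
  distributions are uniform bands that widen toward their common midpoint,
  so at overlap 0 a band threshold separates them exactly (the test suite's
  oracle) and increasing overlap strictly degrades any fixed threshold;
* optional bright stent streaks drawn as thin line segments crossing the
  annulus — a geometric stand-in for metal artifacts, with no CT physics;
* additive Gaussian noise, applied after the mask is fixed, so the ground
  truth marks exactly the pre-noise thrombus pixels;
* a thrombus centroid that drifts smoothly across slices, bounded per slice
  by `center_drift` (the continuous centre moves at most 80% of the bound,
  leaving headroom for rasterization jitter) — this is the coherence the
  Bi-CLSTM exploits;
* one thrombus instance per slice, matching the single-ROI-per-study
  setting.

Cohorts derive per-study seeds by a counter scheme
(`seed + 7919 * i mod 2^31-1`), so any study is reproducible independently
of generation order.

What the phantom does **not** emulate: Hounsfield-accurate tissue models,
beam hardening, reconstruction kernels, anatomy beyond a single vessel, or
inter-annotator variability. Tests passing on phantoms therefore
demonstrate that the machinery learns and evaluates correctly, not that
clinical-grade accuracy is reached on real CTA.

## Numerical and design choices

* **Pair encoding**: image and attention map are stacked as a 2-channel
  input; multiplicative gating of the image by the map was rejected as an
  unsupported extra assumption. Intensities enter the head on the unit
  scale — the residual shortcut is not batch-normalized, and raw 8-bit
  magnitudes would saturate the ConvLSTM gates.
* **Fusion**: concatenation by default (the post-fusion 64-filter
  convolution absorbs the doubled channels); `sum` is kept both as an
  option and because it makes the direction-swap symmetry exactly testable.
* **Peepholes**: on by default, following the original ConvLSTM
  formulation; per-channel rather than per-pixel weights so a trained cell
  transfers across image sizes. A toggle is provided since either variant
  is defensible.
* **Prediction scope**: the head segments only the central (target) slice;
  per-slice inference slides the window so every slice is a target exactly
  once.
* **Initialization**: He-scaled Gaussians for convolutions, forget-gate
  biases at 1, peepholes at 0, batch-norm at identity; the backbone's final
  bias starts at −4 so an untrained provider scores essentially nothing
  above threshold.
* **Focal loss defaults** are α = 0.25, γ = 2 in `head_config()`; the
  desk-scale training runs in the tests and the acceptance script use
  α = 0.75 and larger learning rates (backbone 2, head 1), because with
  mean-reduced losses on small images the reference rates (10⁻⁴ and
  5·10⁻³) move a freshly initialized model far too slowly for runs of a
  few hundred steps. The reference rates remain the configuration
  defaults.
* **Problem sizes**: the validation suite works at 16×16 to 64×64 with
  8/16/8-filter heads — large enough to preserve the structure of the
  computation, small enough for interactive runs. The overfit-capability
  check trains on two noiseless 32×32 phantoms (N = 5, 500 SGD steps) and
  reaches a training Dice above 0.95; the end-to-end check cross-validates
  four noisy phantoms (k = 2) and reaches held-out Dice ≈ 0.8.
* **Determinism**: every stochastic routine takes an explicit seed and
  restores the caller's RNG state; identical configurations produce
  byte-identical cohorts, traces and reports.

## Known limitations

* The detector provider is a contract-faithful lightweight stand-in, not a
  full FPN/RPN instance detector; at clinical resolution its attention maps
  will be weaker than a real detector's.
* Pure-R training is CPU-bound and suited to desk-scale experiments, not
  512×512 clinical volumes with 64/128-filter configurations.
* Batch-normalization statistics follow standard train/eval switching; no
  frozen-statistics mode is offered.
* No surface-distance metrics (Hausdorff, ASSD) and no significance
  testing between methods; the five overlap metrics above are the scope.
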