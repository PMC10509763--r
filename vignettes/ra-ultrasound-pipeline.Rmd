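---
title: "Automatic rectus abdominis segmentation and distance measurement in ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic rectus abdominis segmentation and distance measurement in ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Diastasis recti abdominis (DRA) is a lateral separation of the two rectus
abdominis (RA) muscle bodies, common in postpartum women. The standard
diagnostic measurement is the inter-muscle distance in a transverse B-mode
ultrasound image: separation of 2.5 cm or more confirms DRA. Manual
measurement requires an experienced sonographer, and every patient
contributes many views (several probe locations, several posture states), so
an automatic pipeline is attractive.

`raseg` implements such a pipeline end to end:

1. **Preprocessing** — convert the exported frame (PNG or uncompressed
   DICOM) to a calibrated grayscale image, remove the black annotation
   periphery by Otsu thresholding + largest connected component, and resize
   the cropped scan region to a square model grid.
2. **Segmentation** — an encoder-decoder convolutional network emits a
   per-pixel foreground probability for the RA muscle bodies.
3. **Post-processing** — threshold at 0.5 and keep the two largest
   connected components.
4. **Measurement** — the pixel gap `d` between the bounding rectangles of
   the left and right bodies, converted to physical distance `D = Px * d`
   with `Px` the lateral pixel size in mm after resizing, and classified
   against the 2.5 cm rule.
5. **Evaluation** — Dice, IoU, Hausdorff distance (mm), the average
   physical distance error (APDE) against reference measurements, Pearson
   correlation and Bland-Altman limits of agreement.

Because clinical ultrasound data cannot be redistributed, the package ships
a seeded phantom generator that produces images with exactly known ground
truth; every claim the test suite makes is validated on phantoms.

## The segmentation networks

Three classic architectures are provided through one interface
(`net_config()` + `build_model()`):

* `plain` — the classic U-shaped encoder-decoder: double-convolution
  blocks (3x3 conv, batch norm, ReLU, twice), 2x2 max pooling, 2x2
  transposed-convolution upsampling, and skip concatenation between
  matching resolutions.
* `nested` — a dense-skip variant: intermediate decoder nodes `X[i][j]`
  receive all previous nodes at their resolution plus the upsampled node
  from below, and the deepest top-level node feeds the output head (no deep
  supervision, since the pipeline consumes a single probability map).
* `residual` — the plain topology with every block replaced by a residual
  block (conv-BN-ReLU-conv-BN plus an identity shortcut; a 1x1
  projection + BN where channel counts differ).

All variants use a single-channel sigmoid head: the post-processing step
binarizes one foreground probability map at 0.5, so a two-channel softmax
would be redundant. Inputs are intensities scaled to `[0, 1]`; parameter
initialization is seeded He-normal, so a config + seed pair fully
determines the model. The networks, their backward passes and the Adam
optimizer are implemented in the package itself (R with compiled kernels
for convolution, pooling and transposed convolution); gradient correctness
is verified against finite differences in the test suite.

### Training protocol

`fit()` follows the usual protocol for this task: binary cross-entropy
loss, Adam with learning rate 0.001 and first-moment decay 0.9 (the
"momentum" of the optimizer), batch size 8, up to 100 epochs. After every
epoch the validation set is evaluated in inference mode (no parameter
updates); the parameters with the best validation Dice are kept, and
training stops early after 15 epochs without improvement (patience is
configurable; the scaled-down benchmark uses 5).

Two details are deliberate design choices:

* **Loss.** A foreground-only cross-entropy `-sum(y log x)` admits the
  degenerate all-ones minimizer, so the standard two-term binary
  cross-entropy is used: background errors must be penalized for the
  method to produce bounded muscle regions.
* **Split.** Datasets are split at the *patient* level (default ratio
  7:1:2) so that no patient's images appear in two subsets. Counts follow
  largest-remainder rounding — each subset deviates from its exact
  proportion by at most one patient — with a deterministic repair step
  guaranteeing non-empty subsets from three patients up. Note that for 94
  patients this rule yields 66/9/19; other allocation rules can give
  slightly different counts (e.g. 63/12/19), so the rule used here is
  declared rather than inferred.

### Augmentation

Horizontal flipping (probability 0.5, applied to image and mask) and a
contrast gain drawn uniformly from `[0.7, 1.3]`, applied to the image only,
pivoting at intensity 128 and clipped to `[0, 255]`. The gain range may be
collapsed to a point (`c(1, 1)`) to force a specific gain, which the tests
use to check the identities (no-op, flip involution, pivot invariance).

## Conventions that fix the ambiguous pixel

Several quantities are only defined up to a one-pixel convention; the
package fixes them explicitly so that every value is testable:

* Rectangle bounds are 0-based and **inclusive** throughout.
* The pixel gap is the number of background columns **strictly between**
  the two bounding rectangles: `d = col_min(right) - col_max(left) - 1`,
  clamped at 0 when the column extents touch or overlap. With one region
  (or none) the distance is 0 (invalid when no region survives
  post-processing).
* Binarization is strict (`p > 0.5`); a probability of exactly 0.5 is
  background.
* Otsu ties break toward the lower level; component-area ties break toward
  the smaller leftmost bounding column. Both rules are arbitrary but
  deterministic.
* The DRA rule compares `D >= 25 mm` (threshold and strictness are
  configurable).
* Connected components use 8-connectivity by default (robust to
  antialiased region borders); 4-connectivity is available everywhere.
* Pixel sizes are tracked per axis. Resizing a non-square crop to the
  square model grid is anisotropic, and the *column-axis* (lateral)
  effective pixel size converts the gap to mm, since the RA gap is a
  lateral distance. Physical extent is conserved exactly:
  `new_px = old_px * old_extent / target`.
* Bilinear interpolation (half-pixel-center convention, identity at equal
  sizes) for images; nearest-neighbour for masks so they stay binary.
  Image and mask always undergo the same geometric transform.
* The Hausdorff distance is computed over the full foreground point sets
  (not contours) in mm with per-axis pixel sizes, via an exact Euclidean
  distance transform; the test suite checks it against the brute-force
  max-min definition.
* Dice/IoU of two empty masks is defined as 100 with a warning flag,
  avoiding 0/0 while preserving monotonicity. "MIoU" is reported as the
  single-class foreground IoU (the printed formula); an optional
  `mean_classes = TRUE` flag averages foreground and background IoU.
* APDE uses the absolute difference `mean(p_i * |d_i - dhat_i|)`: an
  "error" must be non-negative.

## The phantom generator

`generate_phantom()` emulates the *content* of a transverse abdominal
B-mode frame, not its physics:

* **Speckle**: the magnitude of a complex Gaussian field smoothed with a
  small Gaussian kernel, normalized to unit mean and scaled by a
  per-tissue-class mean intensity — background tissue 90, muscle interior
  45 (hypoechoic), fascia outline 185 (echogenic). This is the simplest
  texture with ultrasound-like granularity and the correct brightness
  ordering, which the tests assert for every seed.
* **Muscles**: two quasi-elliptical bodies (smooth random radial
  perturbation of a lens shape, star-shaped so rasterization stays
  connected), placed symmetrically about the midline with an exactly known
  number of empty columns between their column extents — the ground-truth
  pixel gap. A zero gap merges the bodies into one connected region.
* **Fascia**: a ~2-pixel bright band around each body (via the distance
  transform), plus optional small bright/dark distractor blobs.
* **Raw mode**: the scan is embedded in a black canvas with the thin
  bright border an acquisition console draws around the imaging area, and
  text-like clusters of bright pixels are scattered in the periphery at
  least 2 px away from the scan region. The embedded rectangle is recorded,
  so the preprocessing crop can be checked for exact recovery.
* **Dataset structure**: one latent gap per patient with 10% per-image
  jitter emulates repeated views; 20% of patients have fully merged
  muscles. Defaults are 128x128 px at 0.5 mm/pixel (a 64 mm field of
  view), 16 mm wide, 9 mm thick muscles, and latent gaps uniform on
  2-30 mm — values chosen once as representative of postpartum abdominal
  wall anatomy at desk scale.

What the phantom does **not** model: attenuation, shadowing, refraction,
curvilinear sector geometry, posture-state deformation, inter-subject
texture variability. Passing the phantom benchmark therefore demonstrates
that the pipeline's machinery is correct and trainable, not that the
shipped defaults reach clinical accuracy on real ultrasound.

## The desk-scale benchmark

`benchmark_end_to_end()` (also run by `scripts/acceptance.R`) trains the
residual variant at depth 3 with 8 base channels on 200 phantom images
(40 patients x 5 views, 128x128) with batch 8 and learning rate 0.001 for
at most 8 epochs (early stop patience 5 on validation Dice, 8 validation
patients), then evaluates the 40 images of 8 held-out test patients. These
problem sizes keep a full run in the tens of minutes on one CPU while
leaving the protocol's structure intact. On this task the network reaches
test Dice above 90%, APDE well under 3 pixels' worth of mm, and a
true-vs-predicted gap correlation above 0.99; the numbers printed by the
acceptance script are recomputed from scratch at every run.

Numerical notes: batch normalization uses biased batch variance, epsilon
`1e-5` and running-statistics momentum 0.1; Adam uses `beta2 = 0.999`,
epsilon `1e-8` and bias correction; predictions are clamped to
`[1e-7, 1 - 1e-7]` inside the loss. All randomness (phantom sampling,
splits, initialization, shuffling, augmentation) flows from explicit seeds,
and two runs with the same seeds are bitwise identical on CPU.

## Known limitations

* The phantom is a structural stand-in; no claim is made about performance
  on clinical images.
* `load_frame()` reads uncompressed little-endian DICOM only — the common
  export format of ultrasound consoles; encapsulated transfer syntaxes
  need prior conversion.
* The measurement is per-image; aggregation of multiple views/postures
  into a per-patient diagnosis is out of scope.
* Training is CPU-bound and sized for small studies; the architecture
  defaults (depth 5, 64 channels) are canonical but were not trained at
  full scale here.
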