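# raseg — rectus abdominis segmentation and distance measurement in ultrasound

Diastasis recti abdominis (DRA) — the lateral separation of the two rectus
abdominis (RA) muscle bodies, common after pregnancy — is diagnosed by
measuring the inter-muscle distance in transverse B-mode ultrasound:
separation ≥ 2.5 cm confirms DRA. Measuring it by hand across the many
views taken per patient is slow and experience-dependent. `raseg` is an R
implementation of a fully automatic pipeline for this measurement, aimed at
researchers who want to study or extend automatic DRA assessment without a
deep-learning framework dependency.

The pipeline:

1. **Load & preprocess** — PNG or uncompressed DICOM frames with
   mm-per-pixel calibration; the black annotation periphery is removed by
   Otsu thresholding + largest connected component, and the cropped scan
   region is resized (bilinear) to a square model grid with exact per-axis
   pixel-size bookkeeping.
2. **Segment** — an encoder–decoder network (plain U-shaped, nested-skip,
   or residual-block variant) emits a per-pixel RA foreground probability.
   Networks, backpropagation and the Adam optimizer are implemented in the
   package (R + compiled kernels), trainable on a CPU.
3. **Post-process** — binarize at 0.5, keep the two largest connected
   components.
4. **Measure** — with two regions, the pixel gap `d` is the number of
   background columns strictly between their bounding rectangles; the
   physical distance is `D = Px · d` (`Px` = lateral pixel size in mm
   after resizing); `D ≥ 25 mm` ⇒ separated. One region ⇒ `d = 0`.
5. **Evaluate** — Dice, IoU, Hausdorff distance (mm, exact distance
   transform), average physical distance error
   `APDE = (1/N) Σ pᵢ·|dᵢ − d̂ᵢ|`, Pearson correlation and Bland–Altman
   limits of agreement (mean ± 1.96·sd).

Because clinical data cannot be shipped, the package includes a seeded
speckle-phantom generator (`generate_phantom()`, `generate_dataset()`)
producing abdominal-ultrasound-like images with exactly known ground-truth
masks and gaps; all tests and the reproducibility script run on phantoms.

## Worked example

```r
library(raseg)

spec   <- phantom_spec(gap_mm = 28, pixel_size_mm = 0.5, seed = 42)
sample <- generate_phantom(spec)
sample
#> <ra_phantom: 128 x 128 px, true gap 56 px (28.00 mm)>

meas <- measure_distance(sample$mask)
meas
#> <ra_measurement: d = 56 px x 0.5 mm/px = 28.00 mm (separated)>
classify_dra(meas)
#> [1] "separated"
```

The requested 28 mm gap becomes 56 empty columns at 0.5 mm/pixel; measuring
the ground-truth mask recovers exactly `d = 56` px, i.e. `D = 28.0` mm,
above the 25 mm threshold, hence `"separated"`. Training and evaluating a
small network end to end:

```r
bm <- benchmark_end_to_end(seed = 1)   # ~6 min on one CPU
bm$eval                                # test-set Dice/IoU/HD/APDE
bm$pearson_true_vs_pred                # agreement with the true gaps
```

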