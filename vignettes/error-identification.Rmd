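---
title: "Dose-comparison inputs for deep-learning error identification in pre-treatment QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-comparison inputs for deep-learning error identification in pre-treatment QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In pre-treatment patient-specific QA, an arc treatment plan is delivered to a
2D detector before the patient is treated, and the measured (or predicted)
dose distribution is compared against the planned one. Classical practice
reduces this comparison to a gamma pass rate under fixed criteria, which
discards most of the 2D information. An alternative is to feed the full 2D
dose-comparison image to a convolutional classifier that identifies *which*
mechanical error occurred (Level 1) and whether its magnitude is clinically
*relevant* (Level 2). The choice of comparison image — gamma map, dose ratio,
dose difference, distance-to-agreement, structural similarity, gradient — and
of the preprocessing (normalization, resolution) then becomes an
experimental design question: which input carries the most information for
the classifier?

`portalQA` implements that whole factorial experiment as a reusable,
seeded pipeline on synthetic data:

1. **plan/dose simulation** — arc plans of MLC-shaped segments, rendered to
   surrogate time-integrated portal-dose images;
2. **error injection** — the five classical mechanical error families with
   their magnitude grids and relevance thresholds;
3. **dose comparison** — twelve 2D comparison-image variants;
4. **preprocessing** — 10% low-dose crop, dataset normalization, square
   resize to 32/64/128;
5. **classification** — a small conv-net with early stopping and optional
   hyperparameter search;
6. **harness** — the 2 × 12 × 2 × 3 factorial (144 cells), cached so all
   cells see identical raw images, with median-per-factor summaries.

## The surrogate dose model

Clinical portal-dose prediction models are machine-specific and not
reproducible from literature. The package instead renders a surrogate that
preserves the *structure* the experiment depends on — aperture geometry, MU
weighting, penumbra, collimator rotation:

\[ D(\mathbf{r}) \;=\; \Big(\sum_s \mathrm{MU}_s \, A_s(\mathbf{r})\Big) * G_\sigma(\mathbf{r}), \]

where \(A_s\) is the fractional-coverage aperture mask of segment \(s\)
(leaves along \(y\), travel along \(x\), rotated by the collimator angle
about the grid centre with bilinear interpolation) and \(G_\sigma\) a
Gaussian penumbra kernel. Dose is therefore exactly linear in MU. The kernel
uses **bin-integrated** Gaussian weights (differences of the normal CDF over
pixel bins), which makes the discrete response to an ideal field edge equal
the analytic error-function profile at pixel centres to truncation accuracy
(radius 6σ, residual < 1e-9) — this is what the renderer's unit oracle
checks. What the surrogate deliberately omits: detector scatter and
response, gantry/EPID sag, measurement noise, off-axis softening. Passing
tests on this surrogate therefore validate the *pipeline*, not any clinical
dose model; accuracies obtained here say nothing quantitative about clinical
plans.

### Generator defaults

The cohort parameters are fixed to the study conditions: per-arc MU drawn
from N(333, 85²) for VMAT-like plans and N(1746, 251²) for SBRT-like plans
(clipped below at 1 MU to avoid degenerate arcs), two arcs per plan, target
field sizes of about 95 × 87 mm (VMAT) and 49 × 47 mm (SBRT) on a
0.8 × 0.8 mm grid at 100 cm source-detector distance. Values the study does
not pin down were chosen once, on physical grounds, and are documented here:

* **segments per arc** 24 — enough modulation for per-segment random errors
  to leave a spatial signature, small enough for desk-scale runtimes;
* **penumbra σ** 3 mm (VMAT) / 2.5 mm (SBRT) — typical portal-image
  penumbra scale;
* **per-leaf edge jitter** SD 1.5 mm and **leaf intrusions** (probability
  0.25, depth up to 0.35 of the field width) — produce modulated,
  segment-varying apertures whose union still approximates the target
  field; leaf travel is clamped to the field ± 3 jitter SD so the aperture
  provably stays inside the dose grid under every tabulated error;
* **per-arc collimator angle** uniform in ±4° — keeps the axis-aligned 10%
  crop box within 15% of the target field size (the module's sanity band)
  while leaving collimator-rotation errors clearly visible;
* **leaves** 5 mm × 22 (VMAT) / 2.5 mm × 24 (SBRT); leaves not fully inside
  the target field height stay closed.

## Error injection

The five error families, their grids and relevance thresholds:

| type | grid (excluding 0) | step | threshold |
|---|---|---|---|
| collimator rotation | −2…+2° | 0.2° | 1° |
| MLC systematic | −2…+2 mm | 0.2 mm | 1 mm |
| MLC random | −2…+2 mm | 0.2 mm | 0.5 mm |
| MU systematic | −10…+10% | 1% | 5% |
| MU random | −10…+10% | 1% | 3% |

Systematic errors apply one magnitude to every segment of an arc; random
errors draw one value per segment (MU) or per leaf and segment (MLC) and
record the realized signed mean as the label magnitude. Design choices made
where the procedure was open:

* **Random-draw law.** Draws are uniform on \([m - s, m + s]\) centred on
  the target magnitude \(m\) with \(s\) = half the type's range. A
  zero-centred law cannot sweep the magnitude grid — its means concentrate
  near zero — while centring on the target reproduces "differed per
  segment, averaged afterwards" and lets realized labels cover the grid.
  The label is always the realized mean (equal to the mean of the stored
  draws to 1e-12, a tested invariant).
* **Threshold convention.** Relevance is inclusive (\(|m| \ge\) threshold):
  the grids contain the thresholds exactly, so a convention is required;
  inclusive keeps the boundary magnitudes in the relevant class.
* **Single-bank sign.** A positive systematic shift of one bank *opens* the
  field; shifting both banks translates the aperture along +x. Overlapping
  pairs clamp to a zero gap at the midpoint, and the count of clamped pairs
  is recorded.
* **Level-2 task.** Binary relevant/irrelevant by default; the joint
  10-class type × relevance labelling is available via
  `makeLabels(..., joint = TRUE)`.
* **No "no-error" class** at either level: the grids exclude zero.

## The twelve comparison images

Gamma maps under (1%,1 mm), (2%,2 mm), (3%,3 mm), (3%,1 mm), (1%,3 mm)
with *global* normalization (dose criterion as a fraction of the maximum
reference dose); dose ratio; absolute and relative dose difference; signed
DTA in x and y (two channels); the relative-DD + DTA stack (three
channels); SSIM; and Sobel gradient magnitude/direction of the relative DD
map (two channels). Numerical conventions:

* **Signed gamma and DD** — the gamma magnitude is multiplied by the sign
  of the local dose difference so over/under-dosage survives into the
  classifier input.
* **Gamma search** — candidates on a grid of pitch/subsample (default 4)
  within radius 3 × DTA, evaluated dose bilinearly interpolated; candidate
  displacements are built as exact pixel fractions so the
  subsample = 1 search is bit-identical to exhaustive pixel search (tested
  against a brute-force oracle on 100 random fields). No low-dose cutoff is
  applied inside gamma; the 10% crop handles low-dose regions.
* **DTA** — per row (x) and column (y), the signed distance to the nearest
  crossing of the local reference dose in the linearly interpolated
  evaluated profile; window W = half the image extent, saturating at ±W
  with the sign of the side of closest dose approach. Flat-region DTA is
  intrinsically ill-conditioned; tests assert translation recovery in
  penumbra regions only.
* **SSIM** — uniform 11 × 11 window, \(k_1 = 0.01\), \(k_2 = 0.03\),
  dynamic range = max reference dose, symmetric padding.
* **Gradient** — Sobel on the *relative* DD map (replicated edges);
  direction is atan2(Gy, Gx), defined as 0 at zero gradient.
* x is the column (horizontal) image axis throughout; the leaf-travel axis.

## Preprocessing

Crop to the bounding box of reference dose ≥ 10% of its maximum (the mask
is defined on the error-free reference dose — the field is a dose concept
and comparison images can be signed); normalize with statistics pooled per
channel over all pixels of the *training* images only (min/max = clip at
mean ± 2 SD then rescale to [0,1]; mean/stdev = standardize); resize each
channel to 32/64/128 square by bilinear interpolation without preserving
aspect ratio (the anisotropic pitch is recorded). Reported pixel sizes
truncate toward zero at one decimal — the only convention consistent with
every tabulated cell of the study's pixel-size table. Statistics never see
validation or test pixels; `evaluateAccuracy` is the only consumer of the
test split.

## Classifier and search

Blocks of two 3 × 3 convolutions + 2 × 2 max-pool, then dense layers and a
softmax — implemented in vectorised base R (no deep-learning framework is
required). Desk-scale defaults: 2 blocks of 8/16 filters, one dense layer
of 32, Adam at 1e-3, batch 32, early stopping on validation loss with
patience 3. The exact clinical-study architectures were never published, so
they live in the hyperparameter search space instead: random sampling by
default, or a Gaussian-process expected-improvement sampler (an internal
RBF-kernel GP) with a median pruner that abandons trials whose validation
loss exceeds the running median at the same epoch. One master seed fans out
to data, split, initialisation and trial seeds; trial t derives from
seed + t so longer searches extend shorter ones trial-for-trial.

## Desk-scale study and what it shows

The full 144-cell factorial at clinical scale needs clinical plans and GPU
budgets. The package's default study is deliberately small: one SBRT-like
cohort (10 plans → 20 arcs, 5 error draws per arc and type on step-doubled
grids → 500 class-balanced images), relative DD at 64 × 64 with mean/stdev
normalization, trained ≈ 2 minutes on one CPU. Under those conditions the
acceptance suite requires Level-1 test accuracy ≥ 60% against a 20% chance
level, chance-level accuracy after label permutation, and — across three
master seeds at 32 × 32 with 200 images — relative DD ranking at or above
DTA-only in at least two of three seeds, mirroring the qualitative factor
ranking (simple direct comparisons beat DTA-only inputs). Nothing in the
suite claims the clinical-scale accuracy magnitudes; those are out of reach
by design.

MU-systematic and MU-random errors are the hardest pair to separate in
time-integrated images: both scale the dose, and the random variant is
distinguishable only through the aperture-weighted residual pattern of its
per-segment draws. Desk-scale accuracies are therefore dominated by that
confusion, which is the expected behaviour, not a defect.

## Degenerate inputs and numerical edges

* Rendering a zero-MU plan returns an exactly zero image; doubling MU
  doubles the image bit-exactly (power-of-two scaling commutes with every
  floating-point step).
* Gamma requires a positive maximum reference dose; relative DD likewise.
* The ratio map falls back to 1 (error-neutral) where the reference is
  below 1e-3 of its maximum.
* SSIM windows larger than the image, empty field masks, apertures leaving
  the dose grid, non-summing split fractions and classes with fewer than
  three items all raise errors rather than degrade silently.
* Bilinear rotation can leave tiny negative dose crumbs; they are clamped
  to zero before the image is constructed.

## Known limitations

No measurement noise, no detector model, no DICOM-RT import, no
time-resolved verification, no 3D dose reconstruction; relevance thresholds
are study conventions, not clinically optimized values. The HDF5 container
of the original design is replaced by a plain directory container
(float TIFF + CSV + YAML), since no HDF5 binding is declared by the
package.
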