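---
title: "Measuring total kidney volume from tracked 3D ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring total kidney volume from tracked 3D ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

In autosomal-dominant polycystic kidney disease (ADPKD), cysts progressively
enlarge both kidneys, and total kidney volume (TKV, the sum of left and right
kidney volumes in mL) is the imaging biomarker used to stage severity and
track progression. MRI is the reference modality, but it is expensive and
impractical for frequent monitoring or pediatric use. A freehand ultrasound
sweep with an electromagnetic probe tracker yields a stack of aligned 2D
B-mode frames — effectively a 3D volume — from which TKV can be measured if
the kidney is segmented on every frame. Manual frame-by-frame tracing is the
bottleneck; `sonotkv` implements the full automated alternative: a
convolutional network segments each frame, segmentations become volumes,
repeated sweeps are aggregated into per-patient TKV, and TKV feeds the Mayo
imaging classification of severity (classes 1A–1E).

Because clinical ultrasound of patients cannot be redistributed, the package
also contains a first-class synthetic phantom generator, so that every stage
— training included — is exercisable and testable from code alone. All
statements below about pipeline behaviour are backed by the test suite or by
`scripts/acceptance.R`; neither this vignette nor the README reports numbers
the code does not compute.

## The phantom: what it emulates and what it does not

A phantom kidney is an ellipsoid (semi-axes $a,b,c$ in mm, Euler-rotated and
translated) carrying spherical cysts expressed in the kidney's local frame.
The sweep geometry is a curved-array sector: a circular sector (apex above
the probe face, angular width, radial depth) replicated across the sweep
axis, with blank lead-in/lead-out frames at the two ends of the sweep.
The B-mode image is synthesized as

* a tissue template (echogenic background, darker kidney parenchyma, bright
  capsule rim where the ellipsoid quadratic form is near 1, strongly
  hypoechoic cysts), Gaussian-smoothed in-plane;
* multiplied by radial depth attenuation $e^{-\mu \rho}$ (default
  $\mu = 0.002$/mm), an exam gain factor (gains drawn in the clinical export
  range 0.54–0.68), and multiplicative Rayleigh speckle of configurable
  contrast — the standard first-order model of fully developed B-mode
  speckle;
* quantized to 8 bits, with everything outside the sector set to zero.

Ground truth is the voxelization of (ellipsoid ∪ cysts) ∩ sector; cysts are
hypoechoic in the image but *remain kidney* in the mask. Alongside the
voxelized mask, `render_phantom()` reports the exact sector-unclipped kidney
volume: closed-form $\tfrac{4}{3}\pi abc$ when cysts are interior (the
sampler only places interior cysts), plus a fine fixed-grid quadrature of any
user-specified protruding cyst material. The tests verify that voxelized
volume converges to this value as spacing shrinks (2, 1, 0.5 mm) and that a
10 mm sphere at 1 mm spacing is within 2% of 4.18879 mL.

Four named acquisition difficulties mirror the conditions that make clinical
sweeps hard: `centered` (benign), `small_fov` (sector depth 145–160 mm
against an enlarged 42–50 mm first semi-axis, so the capsule is clipped),
`low_contrast` (gain pinned at 0.54–0.56 with elevated speckle), and
`oversized` (long axis 136–156 mm exceeding a 125–135 mm sector depth, so
the ground-truth mask itself is clipped by the field of view). All sector
apertures keep in-frame occupancy well above the 20% blank-frame threshold;
clinical sectors occupy a large fraction of the exported frame, and a
"small" field of view is small relative to the organ, not the image. Scan
triples re-render the same kidney with jittered orientation (±6°), gain
(±0.02), placement (±2–3 mm) and aperture (±2°), emulating the protocol in
which each kidney is swept three times.

What the phantom does **not** emulate: wave-propagation physics (no
refraction, shadowing, reverberation or anisotropic point-spread),
probe-pressure deformation, tracker misalignment between frames (slices are
perfectly aligned), neighbouring organs — most importantly no liver, so the
kidney/liver confusion that dominates polycystic-liver cases is out of
reach — and no annotation noise: ground truth is analytic, whereas clinical
reference masks are human tracings with their own variability. Passing the
phantom acceptance experiment therefore demonstrates that the pipeline's
machinery (geometry, learning, inversion, statistics) is correct, not that
clinical-grade accuracy has been achieved on patients.

## Preprocessing: two geometries and 2.5D slabs

Clinical exports are 256² or 512² frames. The pipeline standardizes each
stack to a square *analysis geometry* (default 320 px): smaller frames are
centred in a zero border, larger frames centre-cropped, and a crop that
would remove any foreground voxel of a paired mask is rejected — the kidney
must always be fully included. The *model geometry* (default 256 px) is
reached by bilinear resampling, not cropping: cropping 320→256 could
truncate a large kidney, contradicting the full-inclusion requirement. The
resampling is inverted (bilinearly, recorded per slab) before any volumetry,
so volumes are always measured in the analysis geometry and are not biased
by the model resolution. Mask slices travel by nearest-neighbour resampling
and stay strictly binary; the tests require a 0.95 round-trip Dice on
phantom masks.

Sweeps begin and end with frames recorded before and after organ contact.
The blank-frame filter keeps frame $i$ iff its fraction of non-zero pixels
is **at least** the threshold (default 0.20, inclusive at exactly 20.0%);
it is applied to standardized image frames, not masks, and is idempotent
and monotone in the threshold. The network consumes 2.5D slabs: channels
are frames $(z-1, z, z+1)$ with edge clamping, giving the 2D network local
through-plane context at negligible cost.

## Augmentation

Each training pair yields `multiplier` outputs (default 3: the untouched
pair plus two variants), each variant combining a rotation drawn uniformly
in ±15° with a smooth elastic deformation: control-point displacements
$\mathcal{N}(0, \sigma)$ on a coarse grid (spacing 32 px, $\sigma = 4$ px at
a 256 px slab, both scaled proportionally at other sizes), upsampled with
separable cubic splines. Image channels warp bilinearly, masks
nearest-neighbour, under one shared transform. Defaults keep deformations
anatomy-preserving: augmented mask areas stay within 20% of the original.
Horizontal flip and additive Gaussian noise are implemented but off by
default — flipping confuses anatomically sided kidneys and Gaussian noise
duplicates what speckle already provides.

## The network

A six-level 2D U-Net. Encoder filters double from 32 to 1024; the
convolution kernel is 7×7 at the two top levels, 5×5 at the middle two, and
3×3 at the base, mirrored back up to 7×7 in the decoder. Each level is one
convolution + batch normalization + ReLU; downsampling is 2×2 max-pooling,
upsampling a 2×2 transposed convolution, with encoder–decoder skip
concatenation; a 1×1 convolution with sigmoid produces per-pixel kidney
probabilities. With this block structure the default network has 19.15 M
trainable parameters; a two-convolution block would exceed 22 M under the
same filter/kernel schedule, which is why the single-convolution block was
adopted (the architecture summary returned by `build_unet()` records every
choice for audit). Training minimizes the Dice loss
$1 - (2\sum pt + \varepsilon)/(\sum p + \sum t + \varepsilon)$
($\varepsilon = 10^{-6}$), accumulated over the whole mini-batch, with Adam.
Choices the published setting leaves open, fixed here: batch size 8,
zero-padded convolutions, per-slab intensity scaling by 1/255, binarization
threshold 0.5 (exposed in the config). The clinical-scale defaults (learning
rate $10^{-6}$, 200 epochs) describe a fine-tuning regime that presumes
pretrained weights; `pretrained_weights_path` is the transfer-learning hook,
and desk-scale training from random initialization overrides the rate
upward. The entire engine — forward, backward, batch-norm, Adam — is
implemented natively (Rcpp/Armadillo, im2col + GEMM); its gradients are
verified against central differences to ~1e-8 relative error in the test
suite, and a 200-epoch single-slab overfitting run must reach training Dice
0.95.

Patient-level data discipline is enforced, not assumed: `train_unet()`
rejects any split in which a patient appears on both sides of the
train/validation divide, and `split_cohort()` partitions patients, never
scans (22 patients at 15:2:5 gives 90/12/30 scans).

## Volumetry and agreement statistics

Mask volume is foreground count × voxel volume / 1000 (mL). Per-patient TKV
adds left and right volumes within each scan index and averages across the
three observations; a missing side is a named error, not a silent drop.
Interscan variability is the mean of $|v_i - \bar v|$ over each kidney's
three sweeps, averaged across kidneys (algebraically identical whether or
not one averages per kidney first); kidneys without exactly three sweeps
are excluded with a warning.

Method comparison uses ordinary least squares $R^2$ (free intercept — the
published analysis does not state an origin constraint, and a free intercept
is the conservative default) and percent-scale Bland–Altman:
$d_i = 100\,(m_{1i} - m_{2i}) / \overline{m_i}$, bias $= \bar d$, limits of
agreement $\bar d \pm 1.96\,s_d$ with the $n-1$ sample SD, and a bias CI
$\bar d \pm t_{0.975,\,n-1}\, s_d/\sqrt n$; the bias is "significant" when
zero lies outside that interval. The percent scale makes every quantity
invariant to common rescaling of both series, which the tests assert to
1e-9. Two paired observations suffice for bias and limits (the CI then uses
one degree of freedom); pairs with non-positive means are rejected because
the percent difference is undefined there.

## The evaluation panel

From voxelwise confusion counts (computed in double precision — `tp * tn`
overflows 32-bit integers on full sweeps): DSC $2tp/(2tp+fp+fn)$, Jaccard
$tp/(tp+fp+fn)$ (identically $D/(2-D)$), **FN** interpreted as the
false-negative rate $fn/(tp+fn)$ i.e. 1 − sensitivity (the panel's printed
scale is consistent with this reading, and no other definition matches; the
choice is documented prominently because the label alone is ambiguous), MCC,
and volume similarity $1-|fn-fp|/(2tp+fp+fn)$, which always dominates DSC
($VS - DSC = 2\min(fp,fn)/(2tp+fp+fn) \ge 0$). Degenerate inputs are
flagged, never silently zeroed: two empty masks give DSC 1 with an
`undefined` flag, FN rate is `NA` for an empty reference, MCC is `NA` when a
marginal is empty.

HD-95 is defined here as the 95th percentile of the pooled symmetric
surface-distance distribution — every boundary voxel of each mask (6-
connectivity) to the nearest boundary voxel of the other. The phrase
"average Hausdorff distance with 95th percentile" is ambiguous; the pooled
form is the common HD95, and the directed-average variant is available via
`variant = "directed_average"`. Units default to voxels, with spacing-aware
mm behind `use_spacing` — printed clinical values of order 20 are plausible
in pixels, and the unit choice is left explicit for that reason. ROC AUC is
the rank statistic with tie averaging. Because background dominates a full
sweep, the TN-dependent metrics (MCC, AUC) are evaluated over the kept-frame
domain of the standardized geometry; that convention is fixed and recorded.
Every metric is checked against an independent brute-force implementation
(set arithmetic, explicit neighbour inspection, all-pairs distances,
pairwise concordance counting) on 200 random 8×8×8 mask pairs to 1e-9.

The slice-decile profile splits the reference kidney's sweep extent (first
to last frame with foreground) into 10 contiguous bins, frame $i$ falling in
bin $\lfloor 10(i - z_0)/L\rfloor + 1$, and pools Dice within each bin
(frame-averaging available as an option). End bins carry the smallest
cross-sections and the worst class imbalance, so profiles are expected to
sag at the extremes — the desk-scale experiment asserts centre bins ≥ end
bins.

## Severity classification

The Mayo imaging classification assigns 1A–1E from age and height-adjusted
TKV (htTKV = TKV / height, mL/m). The boundary model is adopted from the
published classification tool: bands of compound annual kidney growth at
1.5/3/4.5/6 %/yr from a 150 mL/m baseline, i.e. thresholds
$150(1+r)^{\text{age}}$; the thresholds live in one isolated function so an
alternative parameterization can be swapped in. Bands are half-open
$[\text{lower}, \text{upper})$: a value exactly on a boundary takes the
higher class, a deliberate, conservative-toward-risk tie rule that matters
because repeated-sweep variability can move borderline patients across
boundaries. Ages ≤ 15 are classified but flagged out-of-domain. Only
typical bilateral (class 1) morphology is modelled. Monotonicity — class
non-decreasing in TKV, non-increasing in age — is property-tested on a
dense grid.

## Cohort summaries

The packaged 22-patient demographics table ships as
`inst/extdata/adpkd_cohort.csv`. BMI categories as printed leave the
interval [24.9, 25) unassigned; the implementation uses contiguous
half-open bands [18.5, 25), [25, 30), ≥ 30, which reproduces all printed
category counts. Display rounding is half-up (R's `round()` is half-even
and representation-sensitive: it turns a median height of 1.675 into 1.67);
raw values are retained, rounding is display-only. The cohort table
contains one internal inconsistency inherited from its source (one age of
75 against a stated maximum of 70); the table is stored verbatim and the
maximum-age statistic is simply not asserted.

## Desk-scale study conditions

The end-to-end experiment (`run_phantom_experiment()`) fixes the following
conditions, chosen once for single-CPU tractability and stated here as the
package's study design: 12 phantom patients (24 kidneys, 72 sweeps) at
128×128×48 voxels of 1.5×1.5×2 mm, difficulty mix
centered/small_fov/low_contrast/centered, patient-level 8/1/3 split;
analysis geometry 128 px, model slabs 64 px; every 4th informative frame
becomes a training slab, augmented ×2; six levels at base 8 filters
(~1.2 M parameters — the "reduced width" desk analogue of the 19 M clinical
network), Adam at 1e-3, batch 8, 8 epochs, best-validation checkpoint.
Prediction always segments *every* informative frame of a test sweep. The
acceptance thresholds this experiment must meet — mean test DSC ≥ 0.85,
|Bland–Altman bias| ≤ 10%, volume $R^2 \ge 0.90$, centre deciles ≥ end
deciles — are properties of the pipeline under these fixed conditions, and
`scripts/acceptance.R --seed S` re-runs the whole experiment from scratch.

## Numerical choices and degenerate inputs

Dice smoothing $\varepsilon = 10^{-6}$; batch-norm $\varepsilon = 10^{-5}$
with momentum 0.1 running statistics; He initialization; Adam
$\beta = (0.9, 0.999)$, $\varepsilon = 10^{-8}$. Bilinear resampling uses
the half-pixel-centre convention (constants map to constants, no corner
bias); warps sample out-of-bounds as zero. All seeded entry points restore
the caller's RNG state, derive child seeds for independent streams, and are
bit-reproducible (asserted for specs, renders, augmentation, splits and
whole experiment reports). Empty stacks, empty masks, single-class
references, non-binary masks, mismatched shapes, missing kidney sides,
overlapping split patients and out-of-range configs are all explicit,
messaged rejections.

## Known limitations

The phantom's realism gap (above) is the main one. The slab engine is
CPU-oriented: clinical-scale training (256 px slabs, 32-base filters, 200
epochs) is expressible but not practical without substantial compute. No
pretrained clinical weights ship with the package — the transfer-learning
hook loads checkpoints produced by `save_unet()` only. Stacks are consumed
as NIfTI; converting scanner DICOM series to NIfTI is an upstream step for
standard tools (dcm2niix, SimpleITK) and is not re-implemented here.
Scanner-specific intensity harmonization and time-gain-compensation
correction are out of scope.
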