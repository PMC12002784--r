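---
title: "Automated 3D prostate and zonal segmentation from transrectal ultrasound: methods"
author: "trusseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated 3D prostate and zonal segmentation from transrectal ultrasound: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trusseg)
```

## The problem

Computer-aided diagnosis of prostate cancer from multiparametric
ultrasound needs the prostate gland — and its transition (TZ) and
peripheral (PZ) zones, which differ in tissue texture and cancer
prevalence — delineated in 3D on both conventional B-mode volumes and
contrast-enhanced ultrasound (CEUS). Manual 3D segmentation takes an
expert on the order of ten minutes per study; an automated pipeline
reduces this to seconds and removes inter-operator variability.
`trusseg` implements such a pipeline end-to-end, together with the
evaluation machinery needed to quantify it and a synthetic phantom
cohort generator that provides exact ground truth for testing.

## Pipeline

The 3D problem is reduced to 2D in a probe-centred cylindrical frame:

1. **Temporal collapse (CEUS only).** A 4D CEUS acquisition (roughly two
   minutes of volumes) is collapsed to a single 3D image by the per-voxel
   arithmetic mean of the contrast intensity over time
   (`temporalMean()`).
2. **Radial resampling.** The volume is resampled into 2D planes that
   contain the probe (z) axis. Plane $k$ lies at azimuth
   $\theta_k = k\,\Delta$; with the default $\Delta = 10°$, 18 planes
   cover the whole cylinder, because each plane's signed radius
   coordinate $s$ also covers $\theta_k + 180°$. A plane point $(s, z)$
   maps to world $(x_0 + s\cos\theta_k,\; y_0 + s\sin\theta_k,\; z)$.
   Every plane comes with two parallel *context planes* offset ±4 mm
   along its normal, which give the network out-of-plane context and
   improve consistency between neighbouring planes. Intensities are
   sampled trilinearly with edge-replicate padding; mask slicing uses
   trilinear sampling followed by a 0.5 threshold.
3. **2D segmentation.** Each plane triple (3 input channels) is fed to a
   small encoder–decoder convolutional network with skip connections and
   two sigmoid output channels: prostate probability and TZ probability.
   One network is trained per modality, because B-mode and CEUS
   appearance differ fundamentally.
4. **Cylindrical reconstruction.** For every output voxel the cylindrical
   coordinates $(r, \theta, z)$ are computed; the two planes that
   angularly bracket $\theta$ (wrap-aware) are sampled bilinearly at
   $(\pm r, z)$ and blended linearly in angle. Interpolation happens in
   probability space *before* thresholding at 0.5 — this is what produces
   a smooth reconstructed boundary. Voxels beyond the sampled cylinder
   radius are background.
5. **Zonal composition.** The TZ is confined to the gland and the PZ is
   its complement within the gland:
   $TZ = TZ_{raw} \cap P$, $PZ = P \setminus TZ$, so the two zones
   always partition the prostate exactly (`composeZones()`). We note
   that a *union* of the gland with the complement of the TZ would
   include all non-prostate tissue; the set-difference reading is the
   only one that yields a peripheral zone, and it is what is
   implemented.

## The network and its training schedule

The network is a conventional U-Net-shaped encoder–decoder built
directly on im2col + GEMM convolution primitives (3×3 kernels, ReLU,
2×2 max pooling, nearest-neighbour upsampling, skip concatenation, 1×1
sigmoid head). The default configuration is **depth 3, base width 8**
(~33k parameters) on roughly 64×64 planes. This is a deliberately
desk-scale choice: the full pipeline — cohort synthesis, training, 3D
reconstruction, evaluation — runs on one CPU core in minutes, which is
what makes the package's end-to-end tests practical, and it is already
sufficient to saturate performance on the synthetic phantoms. Larger
configurations (e.g. depth 4, width 16 or beyond) are reachable through
`modelConfig()`; clinical-scale multi-million-parameter networks are
outside the scope of this package's defaults.

Training follows the study protocol exposed in `trainConfig()`:

* loss: per-channel soft-Dice plus binary cross-entropy (the loss family
  that directly optimises the reported overlap metrics);
* optimiser: Adam, learning rate $10^{-3}$, gradient accumulation over
  batches of 8 planes;
* **fivefold cross-validation** over cases (fold sizes differ by at most
  one; every case is predicted exactly once, by the network that never
  saw it);
* at most **60 iterations** (interpreted as epochs — validation metrics
  are computed per epoch, which is the level at which "no further
  improvement" is meaningful), stopping early when the validation
  metric (mean validation Dice over both channels) has not improved for
  **10 iterations**; the best-epoch weights are retained. The rule is
  exposed as the pure function `stoppingEpoch()` so it can be verified
  in isolation against brute force.
* one master seed drives fold assignment, weight initialisation and
  data order; repeated runs are bit-identical.

The TZ output channel is supervised with the TZ mask over the whole
plane; the PZ is always derived downstream by composition. An
alternative reading — a TZ-vs-PZ discriminator restricted to the gland —
would change only the supervision masks, not the architecture; the
TZ-probability reading was adopted because it keeps the two channels
independent and the composition rule explicit.

## The phantom generator

The generator stands in for a clinical cohort; its defaults are the
package's fixed study conditions.

* **Geometry.** The gland is star-convex: the boundary radius along unit
  direction $u$ is an ellipsoid radius modulated by a smooth random
  perturbation, $R(u) = R_{ell}(u)\,(1 + p(u))$, where $p$ is a seeded
  combination of quadratic/cubic harmonics of the direction cosines with
  $|p| \le$ `perturbationAmplitude` (default 0.08). Star-convexity
  guarantees the radial-plane representation is well posed. The TZ is an
  inner star-convex region anchored toward the anterior-basal aspect of
  the gland and confined within 85% of the boundary radius (so a PZ
  shell of several millimetres always separates it from the capsule);
  its scale is solved by bisection to hit the target TZ volume fraction
  (default 0.4, cohort range 0.30–0.50) within a few percent.
  "Anterior" is the $-y$ direction: the probe sits posterior, at the
  rectum.
* **B-mode appearance.** Piecewise base intensities (background 0.35,
  PZ 0.57, TZ 0.44), a bright rim band (0.92) within 1.2 mm of the
  gland boundary — the capsule is what makes the boundary most distinct
  on B-mode — multiplicative unit-mean gamma speckle (strength 0.25,
  positively skewed like real speckle), and a 0.8 mm Gaussian blur.
* **CEUS appearance.** Distinct zonal enhancement (TZ 0.85, PZ 0.42
  against background 0.12), so zonal contrast is *higher* than on
  B-mode while the outer boundary is *less* distinct; an
  anterior-to-posterior multiplicative suppression gradient (strength
  0.45) emulating the pronounced tissue suppression on the side away
  from the probe; weaker multiplicative noise (0.15); and optional
  slab-wise lateral jitter (0.5 mm) emulating patient motion during the
  two-minute acquisition.
* **Cohort.** `generateCohort()` draws target volumes uniformly within
  the clinical strata — small (< 40 cm³), medium (40–70 cm³), large
  (> 70 cm³), boundaries assigned to "medium" — with margins to the
  cut-offs so that voxelisation cannot flip a stratum, solves the
  semi-axes from the target volume under mildly randomised axis ratios,
  and distributes counts by largest-remainder rounding (51 cases at
  equal thirds give 17/17/17). The default grid is 64³ voxels at
  1.5 mm; everything is a pure function of the seed.

What the phantoms deliberately do **not** model: acoustic wave
propagation, shadowing, refraction, fan-geometry scan conversion,
microbubble kinetics, pathology (tumours, cysts, calcifications), and
inter-patient appearance variability beyond the parameters above.
Passing the end-to-end tests therefore demonstrates that the pipeline's
geometry, learning machinery and metrics are correct and that the
network can exploit realistic contrast structure — not that clinical
accuracy figures would be reproduced on patient data.

## Evaluation suite

Per case and structure, in 2D (per-plane, then averaged over the 18
planes) and 3D:

* **DSC** $= 2|A\cap B|/(|A|+|B|)$ and **IoU** $= |A\cap B|/|A\cup B|$
  (algebraically $IoU = DSC/(2-DSC)$; both are 1 for two empty masks,
  0 when exactly one is empty);
* **RVD** $= (V_{auto}-V_{ref})/V_{ref}\times 100$ — positive when the
  automated mask over-segments;
* **MSD** and **HD** on surface point sets defined as centres of
  foreground voxels with at least one six-connected background
  neighbour; MSD is the symmetric average of the two directed mean
  nearest-neighbour distances, HD the exact symmetric maximum
  (worst-case agreement, not a percentile);
* aggregation: mean with a Student-t 95% confidence interval over
  cases; with fewer than two cases the interval is undefined (NA).

Volume agreement mirrors the clinical comparison against MRI triaxial
measurements: the ellipsoid formula $V = (\pi/6)\,L\,W\,H$, PSA density
$= PSA/V$, Bland-Altman bias and 1.96 SD limits of agreement on
differences taken as (reference-style minus automated, so a larger
reference volume gives a positive bias), and $R^2$ as the squared
Pearson correlation (identical to regression $R^2$ for a simple linear
fit).

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere in 3D, bilinear within planes;
  out-of-volume samples replicate the nearest edge voxel (this avoids
  spurious dark rims at plane borders).
* Probabilities are thresholded at 0.5; reconstruction is monotone in
  this threshold.
* Planes whose pixel grid is not a multiple of $2^{depth-1}$ are
  edge-padded inside the network and cropped on output; inputs smaller
  than $2^{depth}$ per side are rejected.
* `maskToMesh()` extracts the 0.5 level set of a lightly smoothed
  (σ = 0.7 voxel) binary field by marching tetrahedra, giving closed,
  consistently oriented surfaces whose area and divergence-theorem
  volume approximate the underlying smooth shape rather than the voxel
  staircase.
* Both-empty mask pairs score DSC = IoU = 1; surface distances require
  two non-empty masks and error otherwise; RVD requires a non-empty
  reference.
* MetaImage files are read/written uncompressed (MET_SHORT for
  integer-valued data, MET_DOUBLE otherwise); NIfTI carries geometry in
  the sform. Non-axis-aligned direction cosines are accepted on read
  and resampled to the package's axis-aligned frame.

## Problem sizes used in the shipped tests

The test-suite's end-to-end run trains the default network on 40
phantoms (64³ at 1.5 mm, B-mode) for up to 8 epochs and evaluates 10
held-out phantoms; at these sizes the whole suite completes in minutes
on one core while leaving clear headroom above its accuracy thresholds
(mean 3D prostate DSC ≥ 0.85, mean 3D zonal DSC ≥ 0.75, and the zonal
score strictly below the prostate score, reproducing the qualitative
ordering that zones are the harder task). Geometry fidelity is checked
on a 96³ analytic ellipsoid sliced into 9/18/36 planes and
reconstructed (DSC ≥ 0.98 at 18 planes, sub-millimetre MSD, fidelity
non-decreasing in plane count). Metric implementations are verified
against exhaustive brute-force oracles on hundreds of random 16³ mask
pairs.

## Known limitations

* The cylindrical representation undersamples far from the axis; very
  eccentric or off-axis glands would need a repositioned axis
  (`radialGeometry(axisPoint = ...)`).
* The reconstruction assumes the gland is adequately described by the
  18-plane fan; thin protrusions between planes are smoothed away.
* The phantom cohort is a geometric/textural emulation, not an acoustic
  simulation; accuracy numbers on phantoms are upper bounds relative to
  clinical data.
* Training is plain CPU; the default network is intentionally small.
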