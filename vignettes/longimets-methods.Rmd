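---
title: "Methods: longitudinal detection and volumetric quantification of brain metastases"
author: "longimets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal detection and volumetric quantification of brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients treated with stereotactic radiosurgery (SRS) for brain metastases
are followed with contrast-enhanced T1-weighted MRI every few months.
Assessing treatment response means comparing every enhancing lesion in the
new ("current") scan against the pre-treatment ("prior") scan: which lesions
persist and how their volumes changed, which disappeared, and which are new.
Done by hand this is slow and error-prone, particularly with many small
metastases. `longimets` implements a complete automated pipeline for this
comparison, together with the evaluation machinery needed to measure every
stage, and a synthetic phantom generator so that all of it is testable
without clinical data.

The pipeline runs five steps on a scan pair:

1. brain region-of-interest extraction in each scan;
2. rigid registration of the prior scan to the current scan;
3. simultaneous lesion detection and segmentation with a multi-channel
   3D U-Net (SimU-Net-style: the current scan, the registered prior scan and
   optionally the registered prior lesion mask enter as channels of one
   network);
4. lesion matching via a bipartite graph and classification of changes into
   existing / new / disappeared;
5. volumetric quantification of lesions and lesion changes.

## The phantom generator

`phantomConfig()` / `generateStudy()` produce paired longitudinal volumes
with complete ground truth: label masks at both timepoints, the true rigid
inter-scan transform, the true matching edges and the true change class of
every lesion. The scene is analytic — an ellipsoidal "head" of smooth
tissue plus ellipsoidal hyperintense lesions — and is evaluated directly at
world coordinates. The prior volume is rendered at coordinates mapped
through the true transform, so the pair is misaligned by *exactly* the
configured offset and registration accuracy can be scored against a
noise-free reference.

Design choices, and why:

* **Lesions are ellipsoids** with per-axis ratios drawn from [0.7, 1.3]
  (volume-preserving), not irregular blobs. Metastases are characterised
  clinically by sphere-equivalent diameter and volume; analytic shapes keep
  those quantities exact in tests.
* **The head is a single anisotropic ellipsoid** (semi-axes 0.45/0.40/0.34
  of the grid extent). Real heads have no rotational symmetry; a spherical
  phantom would leave rigid rotations unconstrained and make registration
  tests meaningless.
* **Tissue texture** is a smooth sum of three fixed 3D cosines (wavelengths
  29–47 mm, ±15% of the mean tissue intensity), standing in for the
  low-frequency anatomical contrast a registration algorithm actually locks
  onto.
* **Noise is Gaussian** (default sigma 10 a.u. against tissue at 100 a.u.),
  not Rician: at the contrast levels used the difference is immaterial to
  the stages under test.
* **The rendered scene is smoothed with a one-voxel-FWHM Gaussian**
  (sigma about 0.42 voxel) before noise is added, emulating partial-volume
  blur at lesion boundaries. A substantially wider kernel would erode the
  interior of the smallest permitted lesions so far that the generator's own
  contrast contract (mean in-lesion excess of at least 0.8 x contrast) could
  not be honoured; one voxel FWHM keeps boundaries soft while preserving it.
* **Default lesion contrast is 6 noise sigmas**, a clearly enhancing lesion;
  the low-contrast regime (3.5 sigmas) is used in the model-comparison
  experiments where detection is deliberately hard. No intensity statistics
  for clinical T1W-Gad enhancement are claimed; contrast is a free parameter.
* **Default rigid offsets are within a few degrees and millimetres** —
  same-patient head scans are nearly aligned, and within the capture range
  of a rigid registration started at identity.
* **Placement** is rejection sampling (up to 1000 attempts per lesion):
  centres lie inside the head with a margin of at least the lesion radius,
  and distinct lesions keep at least 3 mm of clearance between surfaces
  (regardless of timepoint), so that spatial overlap is a faithful oracle
  for lesion identity.

What the phantom does **not** model: skull and scalp, bias fields, k-space
or motion artifacts, infiltrative lesion margins, mass effect. Passing tests
on phantoms therefore demonstrates the correctness of the pipeline's logic
and the attainable accuracy of its estimators under controlled conditions —
not clinical performance.

## Rigid registration

`estimateRigid()` maximises normalised cross-correlation (NCC) over the six
rigid parameters (Euler angles applied x-then-y-then-z about the moving
image's world centre, plus a world translation) with a three-level
mean-pooling pyramid, central-difference gradients, diagonal-curvature
preconditioning and step-halving line search (tolerance 1e-6 on the
similarity, at most 200 iterations per level). NCC rather than mutual
information because the two scans are the same sequence. Numerical choices
that matter:

* **Pre-smoothing** (sigma 0.8 voxel) removes noise-local optima of the
  similarity.
* **Similarity support**: NCC is evaluated only on the top-decile
  gradient-magnitude voxels of the fixed image. Alignment information is
  concentrated at edges; uniform NCC dilutes it with interior and background
  noise, which measurably displaces the optimum along the soft
  rotation/translation modes.
* **Finest-level polish**: after the pyramid, a quasi-Newton (BFGS) run
  tracks the full six-parameter curvature along the soft coupled
  rotation/translation valleys that axis-wise descent follows too slowly,
  and deterministic perturbed restarts (just under a degree on each rotation
  axis) escape the shallow noise-induced local minima that sit a fraction of
  a degree from the global optimum.
* **Symmetric estimation** (default): the transform is estimated in both
  directions, and the forward, inverted-backward and averaged candidates
  are consolidated by a final optimisation of the summed two-direction
  similarity — two one-way estimates can settle in different noise basins,
  and their plain average then lies on neither objective's floor.
* The rotation centre convention is stated explicitly (moving image's world
  centre) because Euler conventions are a classic source of silent drift;
  `transformMatrix()` is the single authority for the parameterisation.

On default phantoms this recovers offsets up to 5 degrees / 10 mm within
0.5 degrees and half a voxel. Deformable registration is out of scope:
same-patient head scans are relatable by a rigid map.

## The segmentation model

`buildModel()` constructs a 3D U-Net: per level two 3x3x3 convolutions with
ReLU, 2x max-pool downsampling, nearest-neighbour upsampling with a
post-upsampling convolution, skip concatenations, and a final 1x1x1
convolution with per-voxel sigmoid. The 1-, 2- and 3-channel variants differ
*only* in the first convolution (this is asserted by a layer-shape audit in
the tests): channel 1 is the current scan, channel 2 the registered prior
scan, channel 3 the registered prior lesion mask as a {0,1} map resampled
with nearest-neighbour interpolation. Running a 2-channel model on a single
scan duplicated into both channels ("standalone pairs") supports first
timepoints with no prior.

Models with a prior channel emit two output channels (current-scan and
prior-scan lesion probability), since the simultaneous analysis reports
segmentations at both timepoints; the single-channel baseline emits one.

Training (`trainModel()`) uses soft-Dice plus binary cross-entropy with
equal weights, Adam, and seeded patch sampling in which half of the patches
(default) are centred on a ground-truth lesion voxel and the rest uniformly
in the brain ROI — lesions occupy well under 1% of the volume and uniform
sampling would starve the loss. Scans are z-score normalised within the
brain ROI before entering the network (the field offers no single standard
here; the choice is recorded in the run configuration). Everything —
initialisation, sampling order, optimisation — is driven by explicit seeds,
and training is exactly reproducible.

Inference (`predictPair()`) is sliding-window with 50% overlap and
Gaussian-weighted averaging of window probabilities (sigma = window/8),
which removes stitching seams; a window equal to the volume degenerates to
a single forward pass.

The networks here are deliberately small (the test suite uses 3 levels and
4 base filters, about 25k parameters, 32-voxel patches) — sized for
single-CPU reproducibility experiments on phantoms, not for clinical-scale
training, which is explicitly out of scope.

## Lesion extraction and size stratification

`binarize()` thresholds probabilities at 0.5 with ties included (the >= rule
is part of the contract). `extractLesions()` labels 26-connected components
— metastases are compact, and 6-connectivity would split thin diagonal
bridges — removes components whose centroid falls outside the brain ROI and
components below 2 voxels (single-voxel noise), and relabels survivors in
descending volume order with ties broken by lexicographic centroid, so
labellings are deterministic.

Volumes are voxel counts times voxel volume; diameters follow the
sphere-equivalent convention d = (6V/pi)^(1/3), under which 5 mm
corresponds to 0.07 cc and 10 mm to 0.52 cc. Stratification produces the
four standard overlapping classes (>10 mm, >5 mm, <10 mm, All) with strict
inequalities; a lesion of exactly 10 mm belongs to neither strict class —
the convention at the boundary is not standardised anywhere, so the strict
reading is used and documented.

## Matching and change quantification

`buildMatchingGraph()` resamples the prior label mask onto the current grid
(nearest-neighbour) through the rigid transform and creates an edge whenever
a prior and a current lesion share at least one voxel. Lesions left
unmatched by overlap are rescued when their centroid distance is below
max(3 mm, half the sum of their equivalent radii) — thick-slice acquisitions
can leave genuinely corresponding small lesions without voxel overlap.
Rescue edges are flagged (`rescued = TRUE`, overlap 0) so downstream
consumers can distinguish them. Nodes may carry several edges: splits and
merges are legitimate.

Classification is purely topological: matched prior lesions are *existing*,
unmatched prior lesions *disappeared*; matched current lesions *existing*,
unmatched current lesions *new*. The count identities (#prior = existing +
disappeared; #current = existing + new) are enforced by the report class
itself. Quantification groups lesions by connected component of the graph,
so a split lesion is measured jointly rather than per-edge, and reports
summed prior/current volumes, absolute and relative change; groups with no
prior volume report an undefined relative change (NA).

## Evaluation metrics

* Detection precision/recall per scan and size class, with greedy one-to-one
  matching by descending voxel overlap. Size class membership is taken from
  the ground-truth lesion's diameter for true positives and false negatives
  and from the prediction's own diameter for false positives (the only
  diameter a false positive has); a scan with neither ground truth nor
  predictions in a class scores 1.0 on both metrics.
* Dice, with empty-vs-empty defined as 1.0 — stated explicitly because the
  convention silently changes means.
* Average symmetric surface distance in mm, surfaces being mask voxels with
  a 6-neighbour background voxel; empty masks are an error rather than a
  default, because the per-lesion metric is only computed on detected pairs.
* Matching-edge precision/recall (an edge is a true positive iff present in
  both graphs) and per-class change-classification precision/recall, with
  empty classes reported as 1.0 and flagged.
* Scenario comparisons use the Student (pooled-variance) independent
  two-sample t-test, two-tailed, with significance at p < 0.01 — "independent
  t-test" read as the textbook default, not Welch.

Dice, ASSD, detection and edge metrics are each cross-checked in the test
suite against independent brute-force implementations (all-pairs distance
matrices, explicit voxel-set arithmetic) to 1e-9.

## Problem sizes used in the checks

The verification suite runs, by the package's own choice of scale: a
50-study phantom suite for the matching-perfection property (44-voxel
grids; 266 lesions in total, of which 128 existing, 66 disappeared and 72
new); 20 random rigid offsets on 64-voxel phantoms for parameter recovery;
one 64-voxel study, 32-voxel patches and 200 optimisation steps for the
overfitting check; and two trained models (1- and 3-channel) evaluated on
ten 48-voxel low-contrast phantoms for the prior-context precision
comparison. These sizes make every property measurable on a single CPU
while leaving the contracts identical to full-scale runs.

## Known limitations

* The brain ROI is intensity-based (Otsu + morphology), adequate for
  phantoms and for filtering false positives, not a skull-stripping method;
  an externally computed mask can be supplied and simply passes through.
* The matching criterion (any-overlap plus centroid rescue) is the simplest
  rule consistent with split/merge topology; other published rules
  (overlap fractions, dilations) are not claimed to be equivalent.
* Training at clinical scale (large multi-patient cohorts, GPUs,
  augmentation, ensembling) is out of scope; the learning components are
  sized for property-based verification.
* Phantom realism is deliberately limited (see above); no claim about
  clinical detection accuracy follows from phantom results.
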