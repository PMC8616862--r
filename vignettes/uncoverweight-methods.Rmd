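---
title: "Virtual uncovering and weight estimation: models, simulator and design choices"
author: "uncoverweight authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual uncovering and weight estimation: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(uncoverweight)
```

## The problem

Drug dosing and other patient-specific treatments need body weight, which in
emergency and intensive-care settings often cannot be measured: patients are
unconscious, immobile, and — crucially for vision-based estimation — covered
by a blanket. A top-view depth camera sees the blanket's surface, not the
patient, and the apparent volume mixes patient, cover material and the hollow
space tenting between body parts. `uncoverweight` implements a two-stage
volumetric pipeline that addresses the occlusion explicitly rather than
hoping a regressor learns around it:

1. **Virtual uncovering.** A 3D U-Net $f(\cdot;\theta_f)$ maps the binary
   occupancy volume $X^{c} \in \{0,1\}^{h \times w \times d}$ of the covered
   scene to a per-voxel probability volume of the *uncovered* patient
   $X^{\setminus c}$. It is trained on paired covered/uncovered frames of the
   same pose with element-wise binary cross-entropy,
   $\mathcal{L}(\theta_f) = \sum_i \mathrm{CE}\!\left(f(X_i^{c};\theta_f),\, X_i^{\setminus c}\right)$.
2. **Weight regression.** A compact 3D CNN $g(\cdot;\theta_g)$ maps the
   uncovered volume to weight in kg, trained with squared error
   $\sum_i \left[g(f(X_i^{c};\theta_f);\theta_g) - y_i\right]^2$ while
   $\theta_f$ stays frozen.

The decomposition buys interpretability (the intermediate volume can be
inspected) and, empirically, accuracy: a single CNN trained directly on
covered volumes must solve occlusion and regression at once.

## Data representation and preprocessing

Depth frames (pinhole model, depth = $z$ along the optical axis) are
back-projected pixel-wise; `extractBedRegion()` keeps points whose depth
falls in a configured interval and then the largest connected cluster.
Clustering is 8-connected components on the source pixel lattice when the
cloud came from a depth frame — deterministic and fast — with 26-connected
components of occupied 5 cm grid cells as the lattice-free fallback.

`segmentPatientFromBed()` fits the mattress plane by RANSAC (1000 seeded
hypotheses, least-squares refinement on the inliers, inlier tolerance 2 cm)
and removes plane inliers *and* everything below the plane, leaving the
patient's volumetric surface. This segmented cloud is the supervision target
for the U-Net; removing the bed from the target forces the network to
separate patient from mattress, not merely from the blanket.

Clouds are mean-centered (in all three axes) and voxelized into a fixed
cuboid of 1.7 m x 2.4 m x 0.7 m at 48 x 96 x 32 voxels — voxel edges of
about 3.5 cm x 2.5 cm x 2.2 cm, the long axis along the bed — a voxel being
1 iff it contains at least one point. Bins are half-open per axis, so a
point exactly on the cuboid's maximum face is out of bounds (and tallied).
One alignment subtlety: the pair's target cloud is translated by the *input*
cloud's centroid, not its own — the patient-only target has a different
centroid than the bed-region input, and centering each by itself would
misalign supervision by decimeters.

## Architectures

**U-Net.** Four resolution levels; two 3x3x3 conv + batch-norm + ReLU blocks
per level with channels 32/64/128/256; 2x2x2 max-pool downsampling; 2x2x2
transposed-convolution upsampling with skip concatenation; final 1x1x1
convolution to per-voxel logits. On a 48 x 96 x 32 input the bottleneck is
6 x 12 x 4. The output bias is initialized at the logit of the mean target
occupancy, which removes the long "learn the base rate" phase that sparse
voxel targets otherwise impose.

**Weight CNN.** A 5x5x5 stride-2 convolution, then alternating 2x2x2 max
pools and 3x3x3 convolutions — five convolutions with channels
16-24-32-48-64 — for a cumulative downsampling of $2^5 = 32$ per axis
(48 x 96 x 32 ends at 1 x 3 x 1, flattening to 192 features), followed by a
128-neuron fully connected layer, ReLU, dropout $p = 0.8$ and one linear
output neuron. Shape-preserving padding (5 -> 2, 3 -> 1) and floor pooling
make the stated downsampling exact. The output bias starts at the mean
training weight. In classifier mode the output is logistic instead.

The engine behind both networks is a compact volumetric CNN implementation
in this package (im2col + GEMM convolutions in C++/Armadillo, batch norm,
ADAM, milestone learning-rate schedules in R); its gradients are validated
against central finite differences in the test suite. Two numerical choices
of note: training minimizes the fused logit form of the cross-entropy
(mathematically identical to the probability-space form, which `ceLoss()`
implements and the tests cross-check), and losses are per-batch means rather
than dataset sums, so the published learning rate of 0.001 retains its
meaning at any dataset size.

**Schedules.** ADAM, initial learning rate 0.001, batch 16: 50 epochs with a
/10 drop after epoch 30 for the U-Net; 120 epochs with drops at 60 and 100
for the regressor; 10 epochs with drops after 5 and 8 for the cover
classifier. No validation split or early stopping — fixed schedules.

**Regimes.** `trainWeight()` implements three: `two-stage` (the default
pipeline; the regressor consumes the U-Net's *soft* probability volume, and
$\theta_f$ is provably — bitwise — untouched), `plain` (the CNN alone on raw
volumes; on covered input this is the baseline, on uncovered input the upper
bound), and `e2e` (the composition trained on the weight loss only, the
ablation that isolates the value of intermediate supervision). The soft
rather than binarized intermediate volume is used because the end-to-end
baseline needs gradient flow through it, and thresholding discards
calibrated uncertainty the regressor can use.

**Cover detection.** The baseline CNN as a binary classifier (thin and thick
covers pooled as "covered") routes volumes automatically: covered ->
two-stage pipeline, uncovered -> plain regressor. The decision threshold is
0.5 with ties resolving to "uncovered".

## The scene simulator

The clinical dataset the method was designed around is available only on
request, so the package ships a simulator whose output has the same
*structure*: paired frames of an identical body and pose differing only in
cover condition (none / ~1 mm thin / ~3 mm thick material), subjects in
supine and lateral positions, and a weight population with mean 68.0 kg,
sd 12.7 kg, range inside [43.7, 105.1] kg.

**Bodies** are unions of 11 axis-aligned ellipsoids (head, torso, pelvis,
two segments per limb) chained along the bed axis with explicit gaps and a
sufficient separating-axis certificate, so the primitives are pairwise
disjoint and weight = density x sum of ellipsoid volumes *exactly* (density
1000 kg/m^3 by default; only relative recovery matters). A truncated-normal
weight draw is hit exactly by an anisotropic rescale: cross-section scales
with exponent 0.4 per axis and length with 0.2, reflecting that girth varies
much more than stature; the diagonal map preserves disjointness, so the
analytic weight survives. Poses vary by limb splay (supine) and by rolling
primitive centers about the body's long axis with arms placed anterior
(lateral); a deterministic push-apart repair restores disjointness after
randomization without touching volumes.

**The blanket** is a height-field drape: within the coverage region the
covered surface is
$\max(\text{body},\ \text{closing}(\text{body}),\ \text{gauss}(\text{closing}(\text{body}))) + t + \text{folds}$,
with a grayscale morphological closing by an 8 cm disk and 3 cm Gaussian
smoothing (both via EBImage). The closing bridges concavities — the hollow
space under a real blanket between legs, beside arms — which is exactly the
structure that makes covered weight estimation hard; the pointwise maximum
guarantees the cover never dips below body + thickness. Two sources of
between-subject cover variability emulate human-placed blankets, without
which the drape would be a deterministic, effectively invertible function
of the body and the covered condition would lose nothing: the coverage
extent is drawn per subject (55–85% of the bed length from the foot end;
72% is the fixed default when rendering directly), and a nonnegative
low-frequency fold field (1.5 cm amplitude, 8 cm correlation length,
rectified so it never dips below the drape) perturbs the cover surface.

**Rendering** z-buffers the scene height field (bed deck at 2.0 m below the
camera, floor 0.6 m lower, 1 cm field resolution bilinearly supersampled to
5 mm) through pinhole intrinsics (112 x 224 px, focal 160 px) and adds
Gaussian depth noise, sd 5 mm — typical consumer depth-sensor noise — after
z-buffering. The two frames of a pair share one noise realization, so they
are identical outside the blanket, as paired clinical recordings nearly are.
Everything is deterministic given the scene seed.

**What the simulator does not emulate:** cloth dynamics and wrinkles,
articulated self-occlusion, mattress deformation, sensor-specific noise
(flying pixels, shadowing), bed sheets, or a clinically realistic pose
distribution — the pose prior is a stand-in. Passing tests on synthetic
scenes therefore demonstrate that the pipeline's machinery works and that
its qualitative orderings hold under controlled conditions; they are not
evidence of clinical-grade accuracy.

## Evaluation

`evaluatePipeline()` mirrors the published protocol: training is repeated
with distinct seeds; MAE (kg) and MRE (%) are reported per cover condition
(none / thin / thick) and position (supine / lateral, left and right merged)
with mean and sd over repetitions; uncovering quality is measured by Dice
overlap and the *directed* average surface distance from the target volume
to the prediction (6-connected surface voxels, grid border counts as
background, anisotropic voxel sizes, in mm), next to the no-model "initial"
reference between covered input and target. A symmetric surface distance is
available but not the default, matching the directed wording of the
protocol. Dice on an empty reference volume is an error, not 0 or 1 — it
indicates an upstream segmentation failure. Cumulative error distributions
and per-subject averaging over frames (arithmetic mean; the protocol does
not specify the estimator, and the mean is the natural choice for unbiased
per-frame errors) complete the report.

## Desk-scale (reduced) preset

Full-scale training assumes GPU hardware. `reducedRunConfig()` defines the
configuration used by this package's own tests and acceptance script, sized
for a single CPU:

* grid 24 x 48 x 16 over the same cuboid (the coarser grid keeps the
  cuboid geometry; a 24-voxel axis cannot survive five halvings, so the
  reduced weight CNN drops one conv/pool stage: channels 8-16-24-32,
  downsampling $2^4$, head width 64);
* U-Net with base 8 channels (8/16/32/64) — measured throughput on one CPU
  core makes base 16 several times too slow for an interactive test suite,
  and base 8 demonstrably learns the synthetic task;
* 10 U-Net epochs (drop after 7, batch 8), 30 regressor epochs (drops at
  15/25), dropout 0.5 — the 0.8 of the full head is excessive for a
  64-neuron head trained a few hundred steps;
* 300 subjects (240 train / 60 test); the U-Net trains on 144 pairs.

Under these conditions the package's acceptance suite verifies, among
exact unit oracles: that the U-Net at least multiplies the initial
covered-vs-target Dice by 1.5 and reduces the directed surface distance;
that held-out MAE of the plain regressor on uncovered volumes is below half
the population weight sd; that the regime ordering
uncovered <= two-stage <= plain-covered holds in the mean over three seeds;
and that cover detection is error-free and routing exact.

## Known limitations

* The NN engine is CPU-bound and double-precision; it is sized for the
  reduced preset, not for full-scale (48 x 96 x 32, base 32) training.
* Bodies are rigid primitive unions; no articulation between frames of a
  subject, so "45 poses per subject" style replication is emulated by
  independent subjects rather than repeated poses.
* RANSAC plane segmentation assumes the bed plane dominates the bed-region
  cloud; heavily occupied beds (fraction of plane pixels below ~25%) raise
  a segmentation error rather than guessing.
* Multi-camera fusion, temporal tracking, RGB input and cross-domain
  adaptation are out of scope.
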