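---
title: "Restoring LSM brain morphology against MR histology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring LSM brain morphology against MR histology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lsmreg)
```

## The problem

Light-sheet microscopy (LSM) of cleared mouse brains delivers cellular
resolution, but clearing and extraction from the skull distort the tissue:
swelling can exceed 40% locally, anisotropically, and worst in the
olfactory bulb and brain stem; tears and tissue loss are common.  Magnetic
resonance histology (MRH) of the *same* specimen, acquired with the brain
in the skull, preserves the in-vivo-like geometry but at coarser
resolution and with completely different contrast.  `lsmreg` registers
the distorted LSM volume (the *moving* image M) to the MRH volume (the
*fixed* image F), so that cellular measurements can be made in the
in-skull geometry, and atlas labels defined on the MRH can be carried
back onto the uncorrected LSM data.

The workflow has three steps:

1. **Landmark initialization.** 15-20 manually placed pairs (concentrated
   on the olfactory bulb and brain stem, where distortion is worst) seed
   either a least-squares affine or a thin-plate-spline transform.
2. **Staged intensity registration.** A multi-resolution affine stage,
   a symmetric cubic B-spline free-form deformation ("b-spline SyN"),
   and a symmetric diffeomorphic (SyN-style) dense stage, each refining
   the running composite.
3. **Application.** The ordered composite is applied to the
   full-resolution data, optionally in chunks with block reads so the
   moving volume never has to fit in memory.

Throughout, transforms map **fixed-space physical points (mm) into moving
space** -- the resampling convention -- and every stage also produces the
inverse (moving-to-fixed) map, which is what the evaluation loss applies
to fiducials.

## The evaluation loss and the fiducial firewall

Registration quality is scored with paired fiducials (e.g. vessel
bifurcations identified in both modalities): with composite `T` mapping
LSM points into MRH space,

$$ L_2 = \sqrt{\tfrac{1}{n}\sum_i \lVert r_{mr,i} - T(r_{lst,i}) \rVert^2 } $$

the root-mean-square displacement in mm.  Because the prose name
"average displacement" is easily read as the arithmetic mean, both
summaries are returned, explicitly labelled (`$l2`, `$mean`).  Fiducials
are an *evaluation-only* input: `run_pipeline()` has no fiducial
argument, only `sweep_pipelines()` and the evaluation module see them, so
scores measure generalization rather than fitting.

## Similarity metrics

* **MI** -- Parzen joint histogram (linear spreading, default 32 bins;
  16 in the B-spline stage, where coarse levels have few masked voxels),
  entropies in nats.  Intensities are clipped to the 0.5-99.5 percentile
  range; during optimization the range is frozen per pyramid level so the
  objective does not depend on the transform through the histogram
  limits.
* **CC** -- global Pearson correlation.
* **LCC** -- windowed local correlation via box running sums (radius 4
  voxels by default), returned both as a signed mean (the reported
  metric) and as a per-voxel map.  The *force* uses the squared-LCC
  formulation so locally inverted contrast still produces an alignment
  force.
* Masks: voxels outside the supplied brain mask (or where either image is
  background) are excluded from metrics and forces -- tears in the LSM
  make out-of-domain regions common.

All metric gradients are analytic (metric intensity derivative
chain-ruled with the warped image's spatial gradient); the MI gradient is
validated against finite differences in the test suite.

### Local intensity normalization

Both images are locally normalized per pyramid level (subtract Gaussian
local mean, divide by local sd, sigma 8 voxels) before metric evaluation.
This removes smooth multiplicative bias (illumination, attenuation,
staining gradients) that otherwise measurably displaces the MI optimum
away from the geometric optimum.  It can be disabled per stage
(`normalize = FALSE`).

## Registration stages

**Linear stage.**  Rigid or affine parameters anchored at the
fixed-image center, optimized per level by BFGS on the analytic metric
gradient with parameter scaling (matrix entries vs translations).  A
moments initializer (intensity centroid + principal axes) seeds the
search when no landmark initialization is supplied.  We found
derivative-free simplex search unreliable for the 12-parameter affine at
realistic distortions (it failed to recover a 1.2 scale + 10-degree
rotation that the gradient-based optimizer recovers to <1% Frobenius),
which is why the implementation deviates from a plain regular-step
descent.

**Symmetric B-spline stage.**  Two cubic coefficient lattices (fixed-to-
midpoint, moving-to-midpoint) over the fixed extent plus one spline
support of margin.  Forces are least-squares projected onto the basis
through ridge-stabilized normal equations (ridge 1e-3 of the maximal
diagonal); margin controls with under 1% of the maximal data support are
frozen at zero, since their values would otherwise be extrapolation
noise.  The acceptance objective carries a small displacement-magnitude
term (the velocity part of the symmetric energy) so a warp that buys no
similarity is rejected; no explicit bending-energy term is used,
matching the published schedules where spline spacing and the pyramid
are the only regularizers.  One subtlety of histogram metrics is worth
knowing: MI of an image with *itself* can increase under a warp (the
warp reshapes the histogram), so on identical inputs the two half-
lattices can acquire a common-mode displacement -- which the symmetric
composition cancels, leaving the output transform near identity; with
correlation metrics the self-case is exactly stable.  The spline distance (default 26 finest-level voxels)
doubles per coarser level ("fewer control points, then sampled to higher
resolution").  The full forward transform composes the numerically
inverted fixed half with the moving half and is refitted as a single
lattice; building the inverse symmetrically makes swapping the inputs
yield the inverse pair.

**Symmetric diffeomorphic stage.**  Greedy SyN at t = 0.5: both images
warp to the midpoint, symmetric forces are smoothed with `update_sigma`
(fluid-like, default 3 voxels) and composed into each half-field, the
accumulated fields are smoothed with `total_sigma` (elastic-like), and
inverses are produced by fixed-point field inversion.  No time-integrated
geodesic is stored: the energy (velocity magnitude + midpoint
dissimilarity) is decreased greedily, which matches the practical
algorithm behind the published pipeline.

Two numerical choices matter and were set by measurement on phantoms,
mirroring the sweep-the-pipes-and-pick-the-winner procedure of the
original workflow:

* `total_sigma = 1.5` voxels (not the weaker 0.5 sometimes used): with
  weak elastic smoothing the greedy scheme *overfits noise* -- the image
  metric keeps improving while the fiducial error rises, the same
  overfitting reported for the finest-shrink high-resolution pipe in the
  source workflow.
* Both symmetric stages use **greedy descent with move rejection**: a
  trial update is kept only if the (energy) objective strictly improves;
  otherwise the step is halved.  This enforces a monotone energy trace
  and stops the stages from wandering at the metric noise floor on
  already-aligned inputs.  Folding (non-positive Jacobians above 0.1% of
  mask voxels) also rejects the move; persistent folding is an error.

**Stage metrics.**  Defaults follow the similarity sweep winner
(affine MI + B-spline + SyN MI in the presets); LCC (radius 4) remains
the documented choice for contrast-inverted data and is exercised by a
dedicated acceptance property.  On our dual-contrast phantom the
squared-LCC force underperforms MI at multi-voxel misalignment, because
it vanishes wherever the local correlation is near zero -- exactly the
large-residual regime; once alignment is close, LCC and MI behave
similarly.

## Presets and rescaling

`pipeline_preset()` transcribes the published optimization pyramid:
stage-composition candidates `p1_01..p1_06`, similarity candidates
`p2_01..p2_05`, the B-spline multi-resolution winner `p3_42`
(shrink 10x7x4x1, smoothing 4x3x2x1), the spline-distance default
`p4_00` (26), the SyN schedule winner `p5_07` (smoothing 0x0x0x0,
shrink 10x7x4x1) and the high-resolution schedules `p6_03h`, `p6_07h`.
Those schedules assume whole-brain grids, so at run time shrink factors
are clipped to keep at least 8 voxels per axis at the coarsest level,
and the B-spline stage evaluates its finest level at shrink 2 when the
grid would exceed ~200k voxels (the sparse spline basis holds 64 entries
per voxel).  The latter follows the published high-resolution finding
that a finest-shrink-1 B-spline overfits and costs an order of magnitude
more time while the shrink-2 variant does not.

The smoothing integers of the published schedules are interpreted as
Gaussian sigmas in voxels of the *full-resolution* grid, applied before
decimation; whether they were voxels-at-level or mm in the original is
not stated, so the interpretation is a configuration choice, not a fact.

## The phantom generator

`make_phantom()` builds the study conditions: a brain-like anatomy
(hemispheric ellipsoid, two olfactory-bulb lobes, a striped cerebellum
analog with high-contrast granular layers, a brain-stem extension,
curved dentate-gyrus bands, dark vessel trees whose bifurcations anchor
fiducials), rendered twice:

* the **fixed** modality with an MRH-like lookup;
* the **moving** modality with an LSM-like lookup whose contrast is
  *regionally inverted* (bright OB/cortex-dark vs dark OB/bright-center),
  multiplied by a smooth organ-scale bias field (12%) and degraded with
  PSF-correlated Gaussian + Poisson-like noise.

Noise is correlated (0.6-voxel PSF) deliberately: the emulated
acquisitions are heavily averaged (diffusion-weighted averages; LSM
downsampled from micron-scale to registration grids), and white
per-voxel noise would create the well-known interpolation grid artifact
-- a spurious similarity optimum about a voxel away from true alignment
-- that real averaged data does not exhibit at this strength.

The default distortion composes an anisotropic expansion (scales
1.25/1.18/1.10, 4-degree rotation) with smooth Gaussian-bump warps
concentrated on the OB and BS analogs, including a radial OB swelling
term; peak local linear distortion in the OB analog exceeds 40%,
matching the stated regime.  The truth warp evaluates in closed form, so
fiducial and landmark pairs are *exact* by construction (optional jitter
emulates reader placement).  Landmarks in the acceptance scenarios carry
0.1 mm (2-voxel) reader jitter: manual coarse anchors are a few voxels
accurate in practice, and with exact landmarks the affine initialization
is already at the intensity noise floor, which would make staged
refinement meaningless by construction.  Default size is 96^3 at
0.05 mm: large enough for four-level pyramids after the clipping rule,
small enough to generate in seconds.

What the phantom does *not* emulate: light-sheet stripe artifacts,
anisotropic PSFs, real vascular topology, or histology-scale texture.
Passing tests therefore demonstrate correct mechanics and realistic
relative behavior (stage ordering, metric trade-offs, topology
preservation), not absolute accuracy on real tissue.

## Degenerate inputs and numerical guards

* Affine fits reject coplanar landmark configurations (rank check);
  TPS rejects duplicate fixed points.
* Constant images yield MI = 0 with a warning; zero-variance inputs are
  an error for CC and contribute zero windows for LCC.
* Field inversion is fixed-point with 30 iterations and a tolerance of
  0.1 voxel by default; non-convergence warns and returns the best
  iterate with its residual attached.
* Out-of-domain voxels fill with a configurable background (default 0);
  points outside a field's extent clamp (or error when clamping is
  disabled).
* The B-spline stage refuses spline distances below 2 finest-level
  voxels (overfit guard).

## Problem sizes used by the shipped checks

The test-suite and acceptance script run the full staged pipeline once
at 96^3 (0.05 mm), stage-level scenarios at 64^3, and oracle checks at
8-32^3.  Chunked application is verified bitwise at 64^3 and streamed
from disk with block reads; peak block memory is instrumented and
asserted to stay a small fraction of the moving volume.

## Known limitations

* Cross-modality registration accuracy on the phantom bottoms out near
  0.4 voxel (the intensity-information floor of the conditions above);
  fiducial-exactness statements below that scale test the evaluation
  code, not the registration.
* The chunked application contract is implemented over uncompressed
  NIfTI block reads; chunked HDF5 input is not supported in this build.
* No bias-field *estimation* (the local normalization is a fixed
  filter), no Mattes-style stochastic sampling, no GPU path, and no
  oblique acquisition geometries beyond canonical reorientation at load.
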