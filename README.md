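# lsmreg

Cross-modality registration of light-sheet microscopy (LSM) brain volumes
to magnetic resonance histology (MRH) of the same specimen, restoring the
in-skull morphology that clearing and extraction destroy.

Tissue clearing swells and tears the extracted brain — linear distortion
can exceed 40% and is worst in the olfactory bulb and brain stem — so
measurements made on raw LSM volumes inherit that geometry.  MRH acquired
with the brain still in the skull preserves near-in-vivo morphology.
`lsmreg` maps the distorted LSM volume **M** (moving) onto the MRH volume
**F** (fixed) through a staged composite transform:

1. **Landmark initialization** — 15–20 manually placed pairs fit a
   least-squares affine (or thin-plate spline);
2. **Multi-resolution affine** — BFGS on the analytic gradient of mutual
   information (or correlation metrics), coarse-to-fine;
3. **Symmetric B-spline free-form deformation** ("b-spline SyN") — two
   cubic control lattices deform both images toward a midpoint;
4. **Symmetric diffeomorphic matching** (SyN-style, t = 0.5) — dense
   invertible half-fields with fluid/elastic regularization, positive
   Jacobian guaranteed by construction.

Registration quality is scored — never driven — by paired fiducials
(e.g. vessel bifurcations marked in both modalities):

```
L2 = sqrt( (1/n) * sum_i || r_mr,i - T(r_lst,i) ||^2 )      [mm, RMS]
```

where `T` maps LSM points into MRH space.  The package also transfers
atlas labels from the MRH back onto the uncorrected LSM grid (inverse
transform, nearest-neighbor) and computes regional swelling ratios
`(V_before - V_after) / V_MR`.

Everything is exercised end to end on synthetic two-modality brain
phantoms with known ground-truth warps, exact paired fiducials, landmarks
and region labels (`make_phantom()`), so the whole pipeline is testable
without any external data.

## Worked example

```r
library(lsmreg)

# a 96^3 phantom: MRH-like fixed volume, LSM-like moving volume with
# regionally inverted contrast, distorted by an anisotropic swelling
# (up to 40% linear) plus bumps concentrated on the OB/BS analogs;
# landmarks carry 0.1 mm reader jitter
ph <- make_phantom(96, spacing = 0.05, seed = 11,
                   distortion = "default", landmark_jitter = 0.1)

# before registration: RMS fiducial displacement of the raw pair
fiducial_l2(ph$fiducials)$l2
#> [1] 0.4614283            # mm (~9 voxels)

# landmark initialization alone
init <- fit_affine_landmarks(ph$landmarks)
fiducial_l2(ph$fiducials, invert_affine(init))$l2
#> [1] 0.1154813            # mm (~2.3 voxels)

# the staged pipeline (preset p1_02: affine + b-spline SyN + SyN)
res <- run_pipeline(ph$fixed, ph$moving, ph$landmarks, "p1_02",
                    mask = ph$mask)
fiducial_l2(ph$fiducials, res$inverse)$l2
#> [1] 0.05753217           # mm (~1.2 voxels)

# regional error breakdown (cerebellum / olfactory bulb / center / stem)
regional_l2(ph$fiducials, res$inverse)
#>   region  n         l2       mean
#> 1     CB  2 0.07977157 0.07973913
#> 2     OB  1 0.07064355 0.07064355
#> 3      C 53 0.05777360 0.04963151
#> 4     BS  4 0.03153057 0.02917728

# topology: Jacobian determinant of the recovered map is positive
jd <- jacobian_determinant(render_field(res$forward, ph$fixed))
mean(jd$data[ph$mask$data > 0.5] > 0)
#> [1] 1
```

The identity-transform loss (0.46 mm) drops to 0.12 mm after the
landmark affine and to ~0.06 mm (about one voxel) after the full staged
pipeline — the residual is the information floor of cross-modality
intensity matching under the phantom's contrast/bias/noise conditions,
comparable to the ~1.5-voxel vessel-landmark accuracy reported for real
MRH/LSM material.

Labels defined on the fixed grid can be pulled back onto the raw LSM
grid and used for morphometry:

```r
before <- transfer_labels_inverse(ph$labels_fixed, ph$truth,
                                  ph$moving_grid)
volume_ratios(before, ph$labels_fixed, ph$labels_fixed)
# per-region (V_before - V_after) / V_MR, ranked by reference volume
```

## Command line

A thin CLI wraps the same functions:

```sh
exec/lsmreg register --fixed mrh.nii --moving lsm.nii \
    --landmarks lm.csv --preset p1_02 --out run1/
exec/lsmreg apply --manifest run1/forward --in lsm_full.nii \
    --reference mrh.nii --chunk 64 --out corrected.nii
exec/lsmreg sweep --config sweep.yaml --fixed mrh.nii --moving lsm.nii \
    --landmarks lm.csv --fiducials fid.csv --out ranking.csv
exec/lsmreg phantom --size 96 --seed 1 --out phantom/
exec/lsmreg presets show
```

`register` writes the forward and inverse composites as manifest
directories (affine stages as 12-number text, field/B-spline stages as
NIfTI + JSON sidecars, with per-file checksums).  `apply` streams large
uncompressed NIfTI inputs in blocks so the moving volume never has to
fit in memory.

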