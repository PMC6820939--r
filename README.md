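# fidtrack

Estimation of intrafraction rigid motion of liver tumors from implanted
fiducial markers seen in orthogonal stereo kilovoltage (kV) images, as
acquired by robotic radiosurgery image-guidance systems during stereotactic
body radiotherapy (SBRT).

Liver tumors are nearly invisible on kV radiographs, so 3–4 implanted gold
seeds serve as surrogates. Every ~40 s during a ~38 min fraction, two fixed
oblique X-ray sources produce an orthogonal image pair. `fidtrack` converts
each pair into a 3D rigid motion estimate and summarizes fraction- and
cohort-level motion statistics. It is aimed at medical physicists and
methods researchers studying respiratory motion management and PTV margin
design.

## Method

Per acquisition frame:

1. **Marker segmentation** — mean filtering, binarization, 8-connected
   "white blob" extraction with an area filter, blob centroids; detections
   in the two views are paired by their shared superior–inferior (SI)
   coordinate.
2. **3D reconstruction** (parallel-ray): with detector coordinates
   (u_a, v_a) and (u_b, v_b) of one marker,

       (x, y, z)' = Rz(θ) · (u_a, u_b, (v_a + v_b)/2)'

   where Rz(θ) is the z-axis rotation between image and patient frames.
3. **Rigid registration** — the frame's marker set Y is registered to the
   reference frame's set X by minimizing the mean squared residual
   Σ² = (1/n) Σᵢ ‖xᵢ − (R yᵢ + T)‖² over proper rotations. The rotation is
   solved in closed form by the unit-quaternion method: the maximum-
   eigenvalue eigenvector of the symmetric 4×4 matrix built from the
   cross-covariance Σ_yx is the optimal quaternion, and T = μₓ − R μ_y.
   Correspondences come from a nearest-neighbour ICP loop (convergence when
   the RMS residual changes by < 0.001 mm). Unlike the unconstrained SVD
   solution — which, with 3 markers, returns a *reflection* (det = −1)
   about half the time because the centered 3-point cross-covariance is
   singular — the quaternion solution is a proper rotation always.
4. **Motion statistics** — per-frame translations (LR/AP/SI) and extrinsic
   x-y-z Euler angles; per-fraction peak-to-peak ranges with
   Δd = √(Δx² + Δy² + Δz²); cohort mean ± SD of per-fraction ranges; and
   the residual comparison with vs without rotational correction, paired
   t-test per quantity.

A synthetic stereo-imaging simulator (implantation-constrained marker
configurations, breathing-driven sinusoidal motion dominant in SI,
per-marker deformation jitter, rendered detector images) provides ground
truth for every stage.

## Worked example

```r
library(fidtrack)

# one simulated treatment fraction: 57 stereo acquisitions, 40 s apart
cfg   <- simulation_config(n_frames = 57, seed = 1)
sim   <- simulate_fraction(cfg)
trace <- track_fraction(sim)        # segmentation bypassed: coordinate path
round(motion_range(trace), 2)
#>      dx      dy      dz      dd theta_x theta_y theta_z
#>    3.31    5.87   16.48   17.81    6.48    6.62    7.86
```

The fraction's tumor motion spans 3.3 mm left–right, 5.9 mm
anterior–posterior and 16.5 mm superior–inferior (peak-to-peak), combining
to a 17.8 mm 3D range — breathing-dominated SI motion, as expected. A
12-fraction cohort and the residual comparison:

```r
traces <- lapply(1:12, function(s) {
  track_fraction(simulate_fraction(simulation_config(n_frames = 57, seed = s)))
})
summarize_cohort(traces)
#>   quantity  mean    sd unit
#> 1       dx  3.61 0.383   mm
#> 2       dy  6.08 0.380   mm
#> 3       dz 16.32 0.269   mm
#> 4       dd 17.80 0.280   mm
#> 5  theta_x  6.11 0.653  deg
#> 6  theta_y  7.02 0.670  deg
#> 7  theta_z  6.22 0.895  deg
cat(format_residual_table(residual_comparison(traces)), sep = "\n")
#>             w/o rotation   with rotation  p-value
#> |e^x| (mm)   0.79 ± 0.41    0.38 ± 0.18   < 0.001
#> |e^y| (mm)   0.75 ± 0.36    0.34 ± 0.17   < 0.001
#> |e^z| (mm)   0.80 ± 0.41    0.42 ± 0.19   < 0.001
#> |e^d| (mm)   1.54 ± 0.56    0.75 ± 0.24   < 0.001
```

Adding rotational correction roughly halves the residual fiducial
displacement left by a translation-only model (here 1.54 → 0.75 mm in 3D;
the remainder is the simulated non-rigid deformation), and the improvement
is significant in every direction.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fidtrack.R", package="fidtrack"))')" \
    simulate --out run1
Rscript .../fidtrack.R track --in run1 --out run1_results
Rscript .../fidtrack.R summarize --traces run1_results/trace.csv --out cohort
```

`simulate` writes `config.json`, `markers.csv`, `truth.csv`,
`projections.csv` and optional `images/`; `track` writes `trace.csv`,
`registration.json` and `summary.json`; `summarize` writes
`cohort_summary.json` and formatted tables. Every run emits a
`manifest.json`; identical config + seed reruns are byte-identical.

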