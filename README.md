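# lobematch

Non-rigid registration of largely deformed anatomical surfaces, built for the
lung-collapse (pneumothorax) setting: the same lobe is segmented as a closed
triangle mesh in the inflated and the deflated state, the two surfaces share
no vertices or topology, the volume may halve, and the goal is a dense,
smooth, point-to-point displacement field between them. Registered models
share a fixed template topology, so per-subject deformation fields can be
pooled into a statistical deformation model (mean collapse + SVD eigenmodes).

## Who this is for

Researchers analysing organ surface deformation from segmented imaging data —
in particular large deformations with intensity shift, where image-based
registration is unreliable and surface geometry is the robust signal.

## The method

The core is Laplacian-based shape matching with a differential displacement
field (`register_lsmd`). With the uniform discrete Laplacian
`L(v_i) = Σ_{j∈N(i)} ω_ij (v_i − v_j)` (ω = 1), each iteration after affine
pre-alignment:

1. matches every template vertex to the target vertex minimising
   `Q(v_s, v_t) = |v_s − v_t| + γ (1 − n_s · n_t)` (exhaustive search);
2. forms thresholds `Q_high` / `Q_low` as the means of the top 10% / bottom
   2% of the current Q distribution;
3. anchors well-matched vertices (`Q < Q_low`) at their smoothed position
   `v′_s = v_s − λ L(u)` (u = cumulative displacement; smoothing the *field*,
   not the surface) and pulls poorly-matched ones (`Q > Q_high`) a fraction
   `min(l_s/m, 1)` toward the tangent plane of their match;
4. updates the shape by the sparse quadratic solve
   `argmin Σ‖L(v′_i) − L(v_i)‖² + δ Σ‖p_i − v′_i‖²`.

Iteration stops when the best max template-to-target surface distance stops
improving for 10 updates (or at the iteration cap); the best iterate is
returned. Defaults: δ = 10, γ = λ = ω = 1, m = 2.

Also included: the no-field-smoothing ablation (`register_lsm`), piecewise
affine (`register_piecewise_affine`) and global affine (`register_affine`)
baselines; symmetric mean/Hausdorff surface distance, Laplacian-of-
displacement smoothness, target displacement error and lobe-volume metrics;
an SVD deformation model with mode synthesis, variance explained, and
distance-from-hilum linearity analysis; PLY/STL I/O; and a seeded synthetic
lobe generator with analytic ground-truth collapse fields.

## Worked example

```r
library(lobematch)

m   <- make_lobe_mesh(1, n_vertices = 400)          # inflated lobe, 188 cc
out <- apply_deflation(m, deflation_params(
  c = 0.8, rotation_deg = 6, bending = 2, nonlin = 0.03,
  apex_collapse = 0.06, base_collapse = 0.04,
  noise_sd = 0.2, target_n = 520, seed = 42))
volume_ratio(lobe_volume(m), lobe_volume(out$deflated))  # 43.9 (%)

res <- register_lsmd(m, out$deflated,
                     registration_config(max_iterations = 300))
rep <- metric_report(res$mesh, out$deflated, res$displacement)
```

Printed output for this run:

```
deflated volume: 82.6 cc | ratio 43.9 %
MD 0.408 mm | HD 2.495 mm
TDE at tip, ridge-1, ridge-2, ridge-3 : 2.68, 1.1, 0.42, 0.67 mm | mean |u| 11.3 mm
hilum linearity: slope 0.262, R^2 0.942
```

Reading: the deflated target (an independently remeshed surface with 520
vertices — no shared topology) is matched to a mean surface distance of
0.41 mm; the recovered displacement at the auto-placed tip/ridge evaluation
points errs by 0.3–2.7 mm against the generator's analytic ground truth,
against a mean true displacement of 11.3 mm; displacement magnitude grows
almost linearly with distance from the hilum (R² = 0.94), the tether
signature of lobar collapse.

The full desk-scale study — population simulation, template building via
register-and-average, four-method comparison, deformation model — is
`run_experiment(experiment_config())`.

## Command line

```sh
Rscript inst/cli/lobematch.R simulate --cases 11 --seed 7 --out sim/
Rscript inst/cli/lobematch.R register --template sim/case01/inflated.ply \
    --target sim/case01/deflated.ply --method lsmd --out result.ply \
    --trace trace.csv
Rscript inst/cli/lobematch.R evaluate --pair result.ply \
    sim/case01/deflated.ply --displacement result.ply \
    --points sim/case01/points.csv --out report.json
```

Registered meshes are written as PLY with per-vertex `ux uy uz` displacement
properties; a YAML config (field names as in `registration_config()`) can
override any parameter.

## Scope

No image handling, segmentation or surface reconstruction; inputs are closed
triangulated surfaces (PLY/STL, mm). No biomechanical simulation. See
`vignettes/lobematch-methods.Rmd` for the model details, parameter rationale,
synthetic-world assumptions and known limitations — including the one
deliberately failing acceptance test on the four-method ranking.
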