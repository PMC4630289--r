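# somamesh

Automatic repair and soma segmentation of neuronal surface meshes, in R.

Triangular surface meshes of intracellularly injected neurons
(reconstructed from confocal stacks) are usually damaged at the cell body:
the injection leaves **holes and cavities** in the soma surface and
spurious vertices **inside** the cell. Morphometry of the soma — its
volume above all — needs a single closed, artifact-free surface with the
dendrites cut off, and manual cutting varies between (and within) human
raters. `somamesh` implements a deterministic-by-seed pipeline for both
steps, the metrics used to validate such processing, and a synthetic
neuron generator with ground truth so everything is testable without any
data download.

## Method

For a mesh with vertices *i*:

1. **Ambient occlusion** — from each vertex, *N* rays are cast uniformly
   over the hemisphere around its normal; the occlusion factor is
   *A&#7522; = N&#7522;/N*, the fraction that hit the mesh. Exposed surface has
   *A ≈ 0*; vertices lining holes/cavities or trapped inside have *A ≈ 1*.
2. **Automatic threshold** — a two-component 1D Gaussian mixture is fitted
   to the *A* values by EM; the cutoff is the **equiprobable decision
   boundary** (π₁φ(x|μ₁,σ₁) = π₂φ(x|μ₂,σ₂), solved in closed form).
   Vertices above it are removed with their faces.
3. **Closed-surface reconstruction** — an indicator function χ (1 inside,
   0 outside) is recovered from the surviving oriented vertices by solving
   ∇·∇χ = ∇·V on a regular grid (V = splatted inward normals), and the
   isosurface at the mean of χ over the input points is extracted, closing
   all holes.
4. **Shape diameter function (SDF)** — per-vertex local thickness from
   rays cast in a cone around the inward normal to the opposite surface.
5. **Two-step segmentation** — a two-component mixture on the SDF values
   first strips the thin basal dendrites, then (when a dendrite-like
   cluster remains) the apical dendrite; the soma submesh is closed as in
   step 3.

Validation metrics: vertex-to-surface
ϵ(p, S₂) = min<sub>p′∈S₂</sub> d(p, p′), the asymmetric
RMSE(S₁,S₂) = √(Σ<sub>p∈S₁</sub> ϵ(p,S₂)²/|S₁|) and its symmetric form
RMSE_S = max{RMSE(S₁,S₂), RMSE(S₂,S₁)}; and the volume agreement
MAQ₁,₂ = Σ|T₁ᵢ/T₂ᵢ − 1|/M with MAQ_S = max{MAQ₁,₂, MAQ₂,₁}.

## Worked example

```r
library(somamesh)

fx  <- make_neuron()                       # pyramidal-cell fixture, ground truth included
dmg <- inject_defects(fx, hole_cap_degrees = 20, cavity_depth = 1.5,
                      n_interior_points = 50, seed = 3)
is_watertight(dmg$mesh)
#> [1] FALSE

res <- run_pipeline(dmg$mesh, "out", pipeline_config(seed = 5))
mesh_volume(res$soma)
#> [1] 4514.67
4/3 * pi * 10^3                            # ground-truth soma volume
#> [1] 4188.79
```

The damaged fixture (a radius-10 soma with four basal and one apical
dendrite, a 20° hole, a cavity and 50 interior artifact points) comes back
watertight, and the closed soma volume lands within 8% of the analytic
ground truth — the residual is apical-stump mass and reconstruction
smoothing. `out/` holds the repaired mesh, SDF- and label-colored PLYs,
the closed soma and a JSON report with every threshold, seed and count.

Lower-level pieces are exported individually — `occlusion_field()`,
`fit_gmm2()` / `decision_boundary()` (a classed model object with
`print`/`summary`/`coef`/`predict`/`plot`/`simulate` methods),
`reconstruct_closed_surface()`, `sdf_field()`, `segment_soma()`,
`rmse_symmetric()`, `maq()`, `distance_colored_mesh()`, and
PLY/OFF/OBJ/STL I/O via `read_mesh()` / `write_mesh()`. A thin CLI over
the same functions is in `inst/cli/somamesh.R`
(`synth`, `repair`, `segment`, `compare`, `compare-volumes`, `run`).

See the vignette (`vignettes/soma-mesh-repair.Rmd`) for the model
assumptions, the tunables and their defaults, and known limitations.

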