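---
title: "Repairing and segmenting neuronal surface meshes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repairing and segmenting neuronal surface meshes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somamesh)
```

## The problem

Surface meshes of intracellularly injected neurons, reconstructed from
confocal image stacks, are routinely damaged at the cell body: the
injection leaves holes and cavities in the soma surface, and the
reconstruction can place spurious vertices *inside* the cell. Downstream
morphometry — soma volume above all — needs a single closed, artifact-free
soma surface, and needs the soma delimited from its dendrites in a
reproducible way. Manual cutting by neuroanatomists is slow and varies both
between and within raters, so the package implements a fully automatic,
deterministic-by-seed alternative, plus the distance and volume metrics
used to judge any such processing.

Coordinates are treated as dimensionless lengths throughout; confocal
neuron meshes are typically in microns. No unit conversion happens
anywhere.

## Repair

**Ambient occlusion.** For every vertex, `occlusion_field()` samples `N`
directions uniformly (by solid angle, not cosine-weighted) on the
hemisphere oriented along the vertex normal and casts a ray along each.
The occlusion factor is `A = N_hit / N`: close to 0 on exposed surface,
close to 1 for a vertex enclosed by the mesh. Vertices lining holes,
cavities, or floating inside the cell are exactly the dark ones. Rays are
infinite; hits closer than a self-hit epsilon (default `1e-4` of the
bounding-box diagonal) are disregarded so a ray leaving the surface does
not immediately strike its own triangle. The default `N = 128` rays per
vertex keeps the two occlusion populations stable across seeds on the
package's fixtures; it is a tunable, not a law.

**Automatic threshold.** A two-component 1D Gaussian mixture is fitted to
the occlusion values by EM (`fit_gmm2()`), and the cutoff is the
*equiprobable decision boundary* (`decision_boundary()`): the value where
both components have equal posterior probability, obtained in closed form
as the root of a quadratic between the two means. Vertices strictly above
the threshold are removed with their faces (`drop_vertices()`); ties are
kept.

Two numerical details matter here:

* *Variance floor.* EM defaults to flooring component variances at
  `1e-6` times the data variance, which prevents collapse onto duplicated
  values. Occlusion values, however, are count ratios quantized to
  multiples of `1/N`, with a large atom at exactly zero; with the default
  floor, EM collapses one component onto that atom and the boundary hugs
  zero, discarding slightly-shadowed but perfectly good surface. The
  repair stage therefore floors the component standard deviation at half
  the quantization step, `1/(2N)` — below that scale differences between
  occlusion values are not meaningful. On the damaged-sphere fixture this
  moves the threshold from ~0.0007 to ~0.015, keeps false removals at ~4%
  and still removes 100% of injected interior vertices.
* *Low separation.* A fit whose means are closer than one pooled standard
  deviation — the standard deviation of all values pooled together, which
  for a two-component mixture upper-bounds the within-component spread —
  is flagged. A pristine mesh has no artifact cluster: the repair warns
  (and proceeds, near-identity up to reconstruction smoothing) when the
  fit is low-separation or when the above-threshold group is under 1% of
  the vertices.

**Closed-surface reconstruction.** The opened mesh is rebuilt by an
indicator-function (Poisson) reconstruction (`reconstruct_closed_surface()`):
the inward-facing vertex normals are splatted into a regular-grid vector
field V (trilinear weights, then a separable Gaussian of width 1.5 cells),
and the Poisson equation ∇·∇χ = ∇·V is solved matrix-free by conjugate
gradients with Neumann boundary conditions. The isosurface at the mean of
χ over the input points is extracted by marching tetrahedra (the Kuhn
6-tetrahedra cube decomposition), which is watertight by construction
whenever the surface stays inside the padded grid. Stray disconnected
bubbles are dropped (logged). A regular grid (default 96 cells along the
longest axis, 10% padding) replaces the octree of screened-Poisson
implementations: at desk scale the full grid fits comfortably and the
solve is a plain 7-point stencil. The Gaussian splatting means the output
is slightly smoothed — inherent to the method, not a defect. Normals are
re-estimated from the opened mesh before reconstruction rather than
trusting upstream normals.

## Segmentation

**Shape diameter function.** `sdf_field()` estimates local thickness at
each vertex: rays are cast inside a cone (default half-angle 60°, 30 rays)
around the *inward* normal, each ray's length taken to its first hit on
the opposite side. Rays deviating from the median length by more than one
standard deviation are discarded, and the survivors are averaged with
weights inverse to their angle from the cone axis. A mean is used rather
than a raw sum of lengths: a sum scales with the ray count, while the mean
estimates the chord length in length units; the mixture clustering is
invariant to this monotone rescaling. Raw values are clustered without a
log transform (a log scale is available via transforming the field values
if ever needed); on thickness-contrasted neurons two clear Gaussians
appear without it.

Two variance-reduction choices make the per-vertex estimate stable at 30
rays: the polar angle is jitter-stratified over `[0, cone_angle]` rather
than drawn independently (an unlucky independent draw can place the
median so low that the robustness filter discards the near-axial chords —
the most informative ones), and the inverse-angle weight is floored at
one tenth of the cone angle so no single near-axis ray dominates. On a
radius-5 sphere with a 60° cone the 30-ray estimate is 9.50 ± 0.02 across
seeds and agrees with a 10⁴-ray reference to better than 0.05.

**Two-step clustering.** Dendrites are thinner than the soma, so the SDF
distribution separates them. Step 1 fits a two-component mixture to all
values and discards everything below the equiprobable boundary as basal
dendrite. Step 2 refits on the survivors and discards the thinner
component as apical dendrite — unless no dendrite-like structure remains,
in which case nothing is relabeled and the skip is recorded. A fit counts
as *dendrite-like* only if (a) the means are separated by at least one
pooled standard deviation, (b) the upper mean is at least twice the lower
mean, and (c) the thin component carries at least 5% of the mass.
Criteria (b) and (c) go beyond bare separation, and deliberately so: the
smooth thickness gradient where dendrites join the soma can produce a
"separated" two-component fit within the soma itself, and acting on it
would cut the soma in half; requiring dendrite-scale thickness contrast
(a dendrite is at most half as thick as what it is cut from) and
non-negligible mass encodes the premise the whole method rests on. With
thin apical dendrites the apical is typically absorbed together with the
basals in step 1 and step 2 skips — the expected behavior, which the
equal-radius fixture reproduces.

The soma-labeled submesh (faces whose three vertices are all soma;
largest connected component if fragmented) is then closed with the same
reconstruction as the repair stage (`extract_and_close_soma()`).

## Comparison metrics

`rmse(S1, S2)` is the root mean square, over the vertices of S1, of the
minimum Euclidean distance from each vertex to the *full surface* of S2 —
faces, edges and vertices all considered, not nearest-vertex distances.
`rmse_symmetric()` takes the max of both directions, so it is zero exactly
when the surfaces coincide. `maq(v1, v2)` is the mean absolute deviation
from 1 of paired volume quotients (reported as a fraction; multiply by 100
for the percent style), with `maq_sym` its max-symmetrized form.
`distance_colored_mesh()` exports a PLY whose vertices are colored by
(optionally normal-signed) distance to the other mesh, with the ramp
clamped to the 5th–95th percentile of the absolute values; red marks
surface outside the reference, blue inside, green agreement — convenient
for inspecting where two soma cutoffs disagree.

## Synthetic fixtures

`make_neuron()` meshes the implicit union of a spherical soma (default
radius 10) and capsule dendrites — four basal, radius 1, length 25,
pointing into the lower half-space, and one apical, radius 2, length 30,
pointing up — by marching tetrahedra at a default grid spacing of 0.8,
giving roughly 10⁴ vertices. The defaults encode the geometry the method
assumes: an apical thicker than the basals and a soma much thicker than
both; absolute sizes are plausible for pyramidal cells but are the
package's own choice, as is the mesh resolution, picked for desk-scale
runtime. Capsules (hemispherically capped cylinders) stand in for
cylinders because their exact signed distance and volume are closed-form;
the tip shape is irrelevant to the thickness contrast the method uses.
Every vertex carries a ground-truth label from the primitive whose
surface it lies on (ties to soma).

`inject_defects()` emulates injection damage: a spherical-cap hole (faces
deleted), a cavity (a vertex patch displaced inward with a cosine
falloff), and floating interior triangles (artifact vertices), all
recorded with indices in the ground truth and all placed away from
dendrite attachments.

What the fixtures do *not* emulate: imaging noise, fluorescence
inhomogeneity, spines, curved or tapering dendrites, and the irregular,
lumpy somata of real neurons. Passing the fixture suite shows the
machinery is correct on thickness-contrasted geometry with known truth; it
does not certify accuracy on any particular real dataset.

## Numerical choices and degenerate inputs

* EM: k-means++-style initialization, 5 restarts, relative log-likelihood
  tolerance `1e-7`, 500 iterations max; components ordered by mean;
  identical data and seed give identical fits.
* Ties at the threshold are kept (strict `>` removes), matching the
  removal rule's wording.
* `decision_boundary()` errors when no root lies between the means
  (extreme weight/variance asymmetry) and tells the caller to fall back to
  posterior-argmax classification.
* Conjugate gradients: relative residual `1e-8`, cap 3000 iterations; the
  Neumann system's constant null space is handled by zero-meaning the
  right-hand side and solution.
* Watertightness is per-edge (every edge on exactly two faces); volume
  refuses non-watertight input, reporting the boundary-edge count.
* Non-manifold input: duplicate faces and zero-area triangles are dropped
  at load, with a message.
* A single pipeline seed fans out to per-stage sub-seeds by a fixed
  affine-mod derivation, so any stage can be reproduced alone.

## Known limitations

* The regular-grid reconstruction resolves structures a few cells thick.
  At the default 96-cell resolution over a whole neuron, dendrites of
  radius comparable to one cell can fragment or vanish during repair; the
  soma — the target of the pipeline — is unaffected, and all soma-volume
  and recall contracts hold, but the repaired *dendrites* should not be
  used quantitatively. Repairing at higher resolution helps only
  moderately; an octree-refined solver would be the real fix and is out
  of scope.
* The SDF boundary ring where a dendrite meets the soma is assigned by
  the threshold alone; no geometric smoothing of the cut is attempted
  (human raters disagree on exactly these cutoffs too).
* Problem sizes in the test-suite (grid resolutions 48–96, fixtures near
  10⁴ vertices, 64–128 occlusion rays) are the package's desk-scale
  choices; the defaults are the documented ones above.

## A worked example

```{r example, eval = FALSE}
fx <- make_neuron()                      # pristine fixture with ground truth
dmg <- inject_defects(fx, hole_cap_degrees = 20, cavity_depth = 1.5,
                      n_interior_points = 50, seed = 3)
res <- run_pipeline(dmg$mesh, "out", pipeline_config(seed = 5))
mesh_volume(res$soma)                    # ~4/3 * pi * 10^3
rmse_symmetric(fx$mesh, res$repaired)    # sub-cell-size deviation
```
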