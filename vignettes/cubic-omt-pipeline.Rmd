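---
title: "Cubic OMT parameterization of brain volumes: models, parameters, and design choices"
author: "cubeOMT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cubic OMT parameterization of brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Convolutional segmentation networks want dense cubic tensors; a
skull-stripped brain occupies an irregular region covering only 12–20% of
the 240×240×155 acquisition cuboid. This package implements a discrete
optimal-mass-transportation (OMT) parameterization that maps the
tetrahedralized brain volume onto the unit cube $[-\frac12,\frac12]^3$
while (i) minimizing the quadratic transport cost and (ii) preserving the
local mass of a density field derived from the FLAIR grayscale. Because the
map is (approximately) measure-preserving, raising the density on a region
of interest *magnifies* that region in the cube — a magnifying glass for
the tumor — and the inverse map carries voxelwise predictions back to the
brain grid.

# The discrete model

A brain mask is tetrahedralized (each voxel split into 6 Kuhn tetrahedra
with one global diagonal, shared corners merged); the result is a
simplicial 3-complex $\mathcal{M}$ with a closed genus-zero boundary. A
per-vertex density $\rho > 0$ induces simplex densities by corner means,

$$\rho(\alpha) = \tfrac13 \textstyle\sum_i \rho(\hat v_i), \qquad
  \rho(\tau) = \tfrac14 \textstyle\sum_i \rho(v_i),$$

local measures
$a_\rho(\hat v) = \tfrac13\rho(\hat v)\sum_{\hat v \subset \alpha}|\alpha|$
and
$m_\rho(v) = \tfrac14\rho(v)\sum_{v\subset\tau}|\tau|$, and transport costs
$d_\rho(g) = \sum \lVert\hat v - g(\hat v)\rVert^2 a_\rho(\hat v)$ on the
boundary and $c_\rho(f) = \sum \lVert v - f(v)\rVert^2 m_\rho(v)$ in the
volume. The complex is first centralized and rescaled to unit mass
(`normalizeComplex()`), matching the cube's unit volume.

**Boundary map (A-OMT).** The area-measure-preserving boundary map
$g^*_\rho:\partial\mathcal{M}\to\partial\mathcal{C}^3$ is a composition
$(h^*_1)^{-1}\circ h^*_\rho$ of two spherical maps, each computed by
projected gradient descent on the area-weighted stretch energy
$E_S(g) = \frac12\sum_t (\mathbf g^t)^\top L_S(g)\, \mathbf g^t$, whose
weights combine image-triangle cotangents with the local area-stretch
factors $\sigma_{g^{-1}}(\alpha) = \rho(\alpha)|\alpha|/|g(\alpha)|$. Each
iteration takes a gradient step, renormalizes to the unit sphere, and is
accepted only if the energy decreases (otherwise the step is halved), so
the energy trace is monotone by construction.

**Volume map (V-OMT).** The interior map is obtained by homotopy
continuation: the boundary is swept along
$g_\zeta(\hat v) = (1-\zeta)\hat v + \zeta g^*_\rho(\hat v)$ over a uniform
partition $0=\zeta_0<\cdots<\zeta_p=1$, and at each step the interior
solves the Dirichlet problem
$[L_V(f^{(k-1)})]_{II}\,\mathbf f_I^{(k)} =
 -[L_V(f^{(k-1)})]_{IB}\, g_{\zeta_k}$
for the mass-weighted Laplacian $L_V$ whose off-diagonals divide
image-face areas and dihedral cosines by the source mass
$\rho(\tau)|\tau|$. We evaluate the summand through the identity
$|A_i||A_j|\cos\theta = -\tfrac14\, n_i\cdot n_j$ (outward image-face area
vectors), which is cheaper and numerically stabler than assembling areas
and angles separately; the unit tests check it against a literal
evaluation of the printed formula. The diagonal of $L_V$ is the negative
row sum — the formula only defines off-diagonals, and this choice gives a
Laplacian-like operator with the constant-vector kernel that the Dirichlet
problem requires. The interior block is then symmetric positive definite
for nondegenerate iterates and is factorized with a supernodal sparse
Cholesky (sparse LU as fallback).

**Quality diagnostics.** Per map we report the transport cost, the total
mass distortion
$d_\mathcal{M}(f) = \sum_v\sum_{\tau\in\mathcal{N}(v)}
 |\rho(\tau)|\tau| - |f(\tau)||/4$,
the per-vertex local mass ratio over the 1-ring, and the count of folded
image tetrahedra (non-positive signed volume). Folds are counted and
reported, never repaired. For the local ratio $r_f(v)$ two conventions
are conceivable over the 1-ring — the sum and the mean of
$\rho(\tau)|\tau|/|f(\tau)|$; we report the *mean*, which equals 1 under
exact measure preservation and is therefore directly interpretable as a
local distortion factor, and keep the raw sum in the diagnostics
(`localRatioSum`).

# The two-phase density

Modalities are normalized by CEHE — contrast-enhanced histogram
equalization. That name does not pin down a unique algorithm; this
package uses a deterministic reading:
Z-score within the brain mask, clipping at ±3 SD, then within-mask
histogram equalization (empirical CDF) to $[0,1]$, background fixed at 0,
and a constant image degenerating to 0.5. The transform is monotone in the
within-mask ranks, which is the property the density construction needs.
Bit-level agreement with any particular CEHE implementation is therefore
not expected.

*Phase I* builds $\rho_\gamma(v) = \exp(\gamma \bar I_1(i,j,k))$ from the
CEHE FLAIR value of the voxel the vertex borders, with
$\gamma \in [1,2]$ (values outside warn but compute). *Phase II* dilates
the candidate WT region by $m$ voxels (Euclidean ball; default $m=5$),
sets the step field $\exp(\gamma\bar I_1)$ inside the region and 1.0
outside, convolves it with the $m^3$ mean kernel (replicate padding at the
cuboid border), samples it at the vertices, and red-green refines the mesh
on the region so the magnified tumor is also better resolved. Vertex
sampling uses the 0-based half-open voxel convention (a vertex takes the
cell whose minimum corner it is, clamped at the grid border).

# Tensorization and pullback

Cube tensors are built by locating each cube-voxel center in the image
mesh (uniform spatial hash over image tetrahedra; containment with an
$10^{-9}$ barycentric tolerance and a lowest-index tie-break, preferring
positively oriented tetrahedra inside folded regions), pulling the center
back barycentrically, and sampling the source volume at the containing
brain voxel — nearest sampling only, so label cubes stay in their binary
phase alphabet. Cube voxels not covered by the image mesh are zero-filled
and flagged; more than 5% uncovered is treated as a failed map. Phase
label codings follow the region sets WT = {2,1,4}, TC = {1,4}, ET = {4}.

The pullback averages, for each brain voxel $j$, the probabilities of the
$n(j)$ cube centers whose preimages land in it; an uncovered brain voxel
takes the value of the nearest preimage point. Labels are then decided
hierarchically: $p^1_j < \tfrac12 \Rightarrow 0$; else
$p^2_j < \tfrac12 \Rightarrow 2$; else $p^3_j < \tfrac12 \Rightarrow 1$;
else 4; voxels outside the brain stay 0.

# Ensemble voting

For validation the cube is presented in five orientations (identity, 90°
counterclockwise rotation in the axial plane, left-right mirror, top-bottom
mirror, mirror-then-rotation); the axial plane is taken as the first two
tensor axes, a configuration-level convention.
Predictions are inverse-transformed to the reference frame before
comparison. Each prediction is binarized at $\tfrac12$ (the
"Gaussian-bracket" notation is read as thresholding), compared by Dice to
the reference prediction, included iff Dice ≥ 0.8, and the included
probabilities averaged. The reference always votes, so the normalizer is
at least 1.

# The predictor contract and the oracle

Network training is out of scope: a *predictor* is any function
`(cubes, orientation)` returning three probability grids (WT, TC, ET) in
the input's frame. `makeOraclePredictor()` wraps a subject's phase label
cubes as such a function — the label indicator plus clipped Gaussian noise
— so the entire geometry pipeline is testable end to end. The orientation
argument exists so the oracle can present its stored labels in the frame
of the rotated input; a trained network would simply ignore it.

# The phantom

`generatePhantom()` emulates the BraTS layout: a perturbed-ellipsoid brain
whose semi-axes are fractions (0.3875, 0.3333, 0.2968) of the grid
dimensions — giving a resolution-independent brain fraction of about 16%,
inside the 12–20% band — with nested tumor ellipsoids ET ⊂ TC ⊂ WT
(WT semi-axes 0.42 of the brain's, TC 0.7 of WT, ET 0.7 of TC),
FLAIR-hyperintense WT and T1CE-hyperintense ET at ≥ 3 noise SDs of
contrast (tissue means in `phantomSpec()`, noise SD 0.05), and smooth
low-frequency boundary perturbation. Phantoms are bit-deterministic under
the seed. They do **not** emulate bias fields, multi-focal tumors,
anisotropic spacing artifacts, partial-volume effects, or realistic MRI
noise statistics — so passing tests demonstrate the correctness of the
geometry pipeline, not clinical segmentation performance on real data.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1.0 (sweep 1.0, 1.5, 1.75, 2.0) | density exponent; larger values concentrate more cube volume on FLAIR-bright tissue |
| `p` | 11 | homotopy partitions; the continuation reduces mass distortion relative to a single solve |
| `m` | 5 voxels | WT dilation radius and blur kernel size |
| `cubeSize` | 128 | cube tensor resolution |
| `refRes` | 33 | vertices per face edge of the reference cube boundary; finer sharpens $(h^*_1)^{-1}$ at cost of time |
| `aomtIters`, `aomtTol` | 200, 1e-7 | spherical PGM iteration cap and relative-energy stop |
| `residTol` | 1e-8 | relative residual bound for each interior solve |

The recorded network-training defaults (encoder depth 3, initial learning
rate $10^{-4}$, drop factor 0.95, drop period 10, $L_2$ $10^{-4}$, batch
size 8) are configuration metadata only; nothing in this package consumes
them.

# Numerical choices and degenerate inputs

* Mask cleanup keeps the largest 26-connected component and fills interior
  cavities; the genus-zero boundary condition is *checked* (Euler
  characteristic 2, every boundary edge in exactly two faces), not
  assumed.
* The spherical gauge: the stretch-energy minimizer is defined up to
  rotation. We fix it by aligning the $\rho$-weighted principal axes of
  the boundary with the cube axes, assigning each eigenvector to the
  coordinate axis it is already closest to (so the gauge is near-identity
  for axis-aligned shapes) and skipping the rotation entirely when the
  covariance spectrum is within 2% of isotropic — for symmetric shapes the
  principal directions are numerically meaningless.
* The boundary's total $\rho$-area is rescaled to the sphere's area
  ($4\pi$) during the spherical solves and to the cube's surface measure
  (6) for reported area ratios; the volume normalization fixes mass, and
  these boundary rescalings make the area-preservation constraint
  dimensionally consistent.
* Red refinement picks the shortest octahedron diagonal (deterministic
  tie-break); green closure bisects each tetrahedron at its marked edge of
  smallest global index, which keeps shared-face triangulations consistent
  across neighbors without communication.
* Degenerate rules: empty masks error; a constant image under CEHE maps to
  0.5; an empty Phase II region falls back to the Phase I density with a
  warning; empty/empty Dice is 1 and undefined rates are `NA`; HD95 on an
  empty set is an error, surfaced as `NA` in the metrics table.

# Problem sizes in the tests

The test suite and acceptance script run phantoms at 52×52×38 (about
100k tetrahedra before refinement, 450k after), cube tensors at 64³, and
the reference cube boundary at 17 vertices per edge; the full 240×240×155
grid, 128³ cubes, and the 33-vertex reference boundary are the package
defaults for real use. These sizes are the package's choice of desk-scale
study conditions; all properties checked (measure conservation, energy
monotonicity, homotopy benefit, round-trip label fidelity, magnification)
are size-free contracts.

# Known limitations

* Bijectivity of the maps is diagnosed (folding counts), not guaranteed;
  fold counts are mesh-dependent, so they are comparable only between
  runs of this package on the same meshing scheme.
* The A-OMT solver is a first-order projected descent; it inherits the
  usual slow tail convergence of such schemes, and the stopping tolerance
  trades area-preservation sharpness for time.
* CEHE is a documented reading of an under-specified normalization; any
  statistic that depends on exact grayscale values is reproducible only
  within this package.
* Cohort-scale benchmark results on BraTS (network-trained Dice scores,
  transport-cost statistics over hundreds of subjects) require the gated
  dataset and trained networks; this package establishes the geometry
  pipeline's properties at desk scale instead.
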