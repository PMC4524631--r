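---
title: "Simulating the tooth wear process: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the tooth wear process: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothwear)
```

## The problem

Dental attrition — the irreversible loss of enamel and dentin on the chewing
(occlusal) surface — is a decades-long process, but what a clinician or an
anthropologist usually has is just two snapshots: a crown before wear and the
same crown (or a model of it) after wear, digitised as triangle meshes with
unrelated tessellations. `toothwear` reconstructs a plausible, smooth,
anatomically anchored *sequence* of intermediate morphologies between the two
snapshots, together with per-vertex wear-depth maps, and can pace that
sequence with population statistics of wear severity by age.

The pipeline has four stages, each independently callable:

1. **Feature identification** (`extract_feature_points()`): quadric-error
   (QEM) edge-collapse simplification of the intact crown; the vertices that
   survive aggressive decimation sit on the shape-defining anatomy (cusp
   apices, ridges, groove floors) and are mapped back to exact vertices of
   the input surface.
2. **Selective alignment** (`align_axial()`): point-to-point ICP fitted
   *only* on the axial (side-wall) region, which wear does not change, then
   applied to the whole intact mesh. Closest points are taken on the target
   surface (point to triangle), so the result does not depend on the worn
   scan's tessellation density.
3. **Homogeneous surface** (`build_initial_homogeneous()`,
   `contract_and_bound()`): a mesh with the intact crown's connectivity whose
   geometry coincides with the worn scan. The feature points are projected
   along their vertex normals onto the worn surface; the signed projection
   distances are interpolated by a cubic radial basis function field
   \(D(x) = \sum_j \lambda_j \lVert x - V_j \rVert^3 + c_0 + c_1 x + c_2 y +
   c_3 z\) subject to the four orthogonality conditions
   \(\sum_j \lambda_j = \sum_j \lambda_j V_j^{x,y,z} = 0\); evaluating the
   field at every intact vertex and offsetting along the vertex normal gives
   the initial guess, which a contraction-and-bounding iteration
   (\(P_i' = P_i + \lambda (Q_i - P_i)\), \(\lambda = 0.4\), with 1-ring
   smoothing) converges onto the worn surface until the summed error
   \(E = \sum_i \lvert P_i - Q_i \rvert\) falls below \(\epsilon = 0.001\).
4. **Morphing** (`morph_sequence()`): both endpoint surfaces are written in
   uniform-weight Laplacian differential coordinates
   \(\delta_i = v_i - \tfrac{1}{d_i}\sum_{j \in N(i)} v_j\); for each
   interpolation factor \(u\) the *direction* and *magnitude* of each
   \(\delta_i\) are interpolated separately
   (\(\delta_{MU} = (1-u)\hat\delta_S + u\hat\delta_T\),
   \(\lvert\delta_M\rvert = (1-u)\lvert\delta_S\rvert +
   u\lvert\delta_T\rvert\), \(\delta_M = \lvert\delta_M\rvert\,\delta_{MU}\)),
   and world coordinates are recovered by solving the sparse system
   \(L V = \delta_M\) with the axial vertices as positional anchors.

A fifth, independent component (`fit_dcf()`, `nonlinear_schedule()`) turns a
table of mean attrition index by age into a **dynamic control function**:
both columns are min-max normalised to \([0,1]\) and fitted with a
least-squares cubic \(u(t)\), which replaces the uniform \(u\) grid with an
age-realistic schedule — fast wear in youth (immature enamel), a long stable
plateau (fully mineralised enamel), and accelerating wear once dentin is
exposed.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `n_features` | 150 | count | RBF centers; enough to cover every cusp, ridge and groove of a molar-scale crown |
| `lambda` | 0.4 | — | contraction factor per iteration; smaller values reduce the risk of self-intersection at the cost of more iterations |
| `epsilon` | 0.001 | mm | stopping threshold on the *summed* error \(E\); it scales with the vertex count (`mean_error = TRUE` switches to \(E/m\)) |
| `smoothing_weight` | 0.5 | — | 1-ring blend applied to the contraction displacement field |
| `max_iterations` | 50 | count | iteration cap; on the standard synthetic pair the summed rule needs \(\approx 55\) iterations, so convergence-critical runs raise the cap (the cap is plumbing, not physics) |
| anchor weight | `Inf` | — | axial anchoring in reconstruction; `Inf` pins the axial wall exactly |
| DCF degree | 3 | — | cubic is the lowest degree able to express the three wear phases |

## What the smoothing step smooths

The contraction update is followed by "1-ring weighted smoothing". Smoothing
the vertex *positions* (the textbook umbrella step) biases every vertex off
the target by the local curvature: the 1-ring centroid of points on a curved
surface lies off the surface by \(O(h^2\kappa)\), which on a few-thousand-
vertex crown floors the summed error at \(E = O(10)\) — the iteration could
never reach \(\epsilon = 0.001\). We therefore smooth the per-vertex
contraction *displacements* \(d_i = \lambda (Q_i - P_i)\) (blending each with
its 1-ring average) instead of the positions. This keeps the regularising
effect on the update field, but the projection fixed point \(P_i = Q_i\) is
undisturbed, so \(E\) contracts geometrically all the way down to the
stopping rule. The positional variant remains available
(`smooth_positions = TRUE`) for users who want triangle-quality smoothing
and a mean-error stopping rule.

## Anchoring the reconstruction

The uniform Laplacian annihilates constants, so \(LV = \delta\) alone
determines the surface only up to translation. The axial wall is physically
unchanged by occlusal wear, which makes it the natural Dirichlet region. Soft
anchor rows with a finite weight trade anchor fidelity against the
differential coordinates and leave the wall drifting by \(\sim 10^{-4}\) mm
per frame; since the wall must be *exactly* stationary across frames, the
default anchors are hard: anchored vertices are substituted into the
right-hand side and only the free vertices are solved for (sparse normal
equations, Cholesky). Finite weights remain available through
`anchor_set(weight = )`.

## Numerical choices

* **Direction interpolation is literal.** \(\delta_{MU}\) is the convex
  combination of the two unit vectors and is *not* renormalised before being
  scaled by the interpolated magnitude; `renormalize = TRUE` offers the
  common variant. Endpoints are exact either way.
* **Zero-magnitude deltas** (a vertex exactly at its 1-ring centroid) have
  no direction; such vertices fall back to plain linear interpolation of the
  raw vectors.
* **QEM ties** are broken by the lowest edge index, and collapses that would
  break edge-manifoldness (link condition) or fold a face are skipped, so
  simplification is deterministic and topology-safe. Open borders carry
  perpendicular constraint planes (weight \(10^3 \times\) squared edge
  length) so a real scan border may only be simplified along itself; for
  *region-restricted* extraction the cut border is an artefact of the mask,
  so there the constraints are disabled — otherwise the whole feature budget
  is spent on the cut edge rather than on anatomy.
* **Signed distances.** Wear is material loss; the feature distances are
  signed by the projection direction (negative against the outward normal),
  so the RBF field moves vertices inward where material was lost and the
  orthogonality conditions keep the field affine-exact.
* **Projection** casts the line \(p + t\,n\) against every target triangle
  and keeps the hit with smallest \(\lvert t \rvert\); a point whose line
  misses the target entirely falls back to the closest surface point and is
  flagged. Kernels are compiled (C++) with a bounding-sphere prune.
* **ICP stopping** is on the change of the RMS closest-point distance,
  default \(10^{-6}\) mm; noiseless benchmark recoveries run the iteration
  essentially to fixed point (tolerance \(10^{-12}\)–\(10^{-15}\)).

## The synthetic tooth and what it does (not) show

No reference scans ship with the package; every test runs on a parametric
crown (`generate_tooth()`): a height field over a lobed disk — Gaussian cusp
bumps on a shallow dome with a central fossa — extruded downward into a
vertical axial skirt. The lobed (squarish) cross-section matters: molar
crowns are not surfaces of revolution, and without the lobes a rotation
about the tooth axis would be invisible to surface registration. Wear is a
known smooth depth field (uniform, or Gaussian facets centred on the cusp
apices, tapered to zero at the crown margin) applied along the analytic
surface normal; the worn counterpart can be re-sampled on an independent,
denser, jittered vertex layout so that — like a second scan — it shares no
vertex correspondence with the intact mesh, while both tessellations sample
the identical continuous worn surface. Ground truth depth is returned on the
intact tessellation, which is what the pipeline's recovered wear map is
checked against (mean absolute error below 0.02 mm on the standard pair).

The generator emulates the geometry of the problem — anatomy-scale curvature
landmarks, unequal tessellations, an unchanged axial skirt — but not scanner
noise, holes, or the fine texture of real enamel, and its wear field is
smooth by construction. Passing tests therefore demonstrate the numerical
correctness and convergence of the pipeline, not robustness to defective
scans.

Standard problem sizes used throughout the tests: crowns of roughly 2,000
vertices (about 1,400 occlusal) with 150 feature points for end-to-end runs,
300–800 vertices for unit-level geometry checks. On the standard pair the
contraction reaches \(E < 0.001\) in about 55 iterations and the mean
per-vertex projection distance at termination is \(\approx 7 \times 10^{-7}\)
mm.

## A worked run

```{r, eval = FALSE}
s0 <- generate_tooth(tooth_spec(n_cusps = 5, resolution = 2000, seed = 1))
w  <- apply_wear(s0, wear_field_spec(max_depth = 0.5), retessellate = TRUE)

al <- align_axial(s0, w$worn)
hz <- homogenize(al$mesh, w$worn, n_features = 150,
                 params = contraction_params(max_iterations = 150))

dcf <- fit_dcf(normalize_minmax(attrition_table_lower_molar()))
u   <- nonlinear_schedule(dcf, 6)
frames <- morph_sequence(al$mesh, hz$mesh, u)
```

## Known limitations

* The morph is a geometric interpolation; it contains no contact mechanics,
  enamel anisotropy or load modelling — nonlinearity in time enters only
  through the fitted control function.
* Self-intersection of the homogeneous surface is discouraged by the
  contraction factor, not excluded; `self_intersection_count()` audits it.
* The clamp of \(u(t)\) into \([0,1]\) (the fitted cubic gives
  \(u(0) = -0.013\) and \(u(1) = 0.977\)) and the cumulative-max
  monotonisation of schedules are pragmatic guards, logged when they bite.
* Point-to-point ICP assumes the two casts are roughly posed; there is no
  global initialisation.
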