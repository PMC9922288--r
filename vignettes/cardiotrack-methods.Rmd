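---
title: "Tracking left-heart wall motion and computing transmitral and LAA flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking left-heart wall motion and computing transmitral and LAA flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Time-resolved cardiac CT reconstructs the beating left heart as ~20 phases
per cardiac cycle (0–95% of the RR interval in 5% steps). Each phase yields
a surface of the contrast-enhanced blood pool, but the surfaces have no
point correspondence across phases. To derive wall motion — and from it
chamber volume curves, transmitral (mitral valve, MV) flow and left atrial
appendage (LAA) flow — a *source* surface with fixed topology must be
deformed frame-by-frame onto each phase's *target* surface.

`cardiotrack` implements this pipeline: optimal-step nonrigid iterative
closest point (N-ICP) registration with stiffness, landmark and
bi-directional terms; chain-wise tracking through the cycle with the LAA
registered separately; cubic B-spline temporal smoothing; divergence-theorem
volumetry on a 5 ms grid; and flow-rate curves with their clinical indices.

## The registration model

The unknown is a stack $X$ of per-vertex affine transforms: each source
vertex $i$ owns a $4\times3$ block $X_i$, and its deformed position is
$[x_i\,y_i\,z_i\,1]\,X_i$. One *optimal step* minimizes the stacked linear
least-squares cost

$$
E(X)=\left\lVert
\begin{bmatrix}\alpha\,M\otimes G\\ W D\\ \beta D_L\\ \lambda D_{Tar}\end{bmatrix}X-
\begin{bmatrix}0\\ W U\\ \beta U_L\\ \lambda U_{Tar}\end{bmatrix}
\right\rVert_F^2
$$

* **Stiffness** ($\alpha\,M\otimes G$): $M$ is the node-arc incidence matrix
  (one row per mesh edge, $-1/+1$ entries), $G=\mathrm{diag}(1,1,1,\gamma)$
  with $\gamma=1$. Penalizes differences between neighboring vertices'
  transforms; any *global* affine (translation, rotation, uniform scaling)
  is cost-free.
* **Distance** ($WD$ vs $WU$): $D$ holds homogeneous source coordinates,
  $U$ the nearest *target vertex* of each deformed source vertex, $W$ is a
  0/1 diagonal (0 exactly for landmark vertices).
* **Landmarks** ($\beta D_L$ vs $\beta U_L$), $\beta=10$: soft prescription
  of selected vertex positions — vessel-cut boundary rings frozen at their
  reference positions, and the LAA ostium ring prescribed from the chamber
  pass when registering the LAA alone.
* **Bi-directional** ($\lambda D_{Tar}$ vs $\lambda U_{Tar}$),
  $\lambda=0.5$: for a subsample of target vertices (greedy selection, no
  two closer than 5% of the target's bounding-box diagonal), the nearest
  *source* vertex is pulled toward the target point. This counteracts the
  collapse tendency of one-directional closest-point matching on the
  strongly deforming LAA; it is enabled for LAA passes.

The stiffness weight is annealed: 100 → 1 in 100 uniform steps for the
chamber (LA+LV) passes, 100 → 10 in 20 steps for the LAA. Within each
stiffness value the loop alternates correspondence search and the exact
sparse least-squares solve (normal equations, sparse Cholesky) until
$\lVert X_j - X_{j-1}\rVert_F < \varepsilon$ (default $10^{-4}$ in
normalized coordinates) or 10 inner iterations. All geometry is first
scaled jointly into the unit cube, computed once from the source frame —
a per-frame rescale would corrupt the very volume changes being measured.

### Numerical choices

* The solve uses `Matrix::solve(crossprod(A), crossprod(A, B))`; for
  $\alpha>0$ on a connected mesh the normal matrix is SPD. A singular
  system (disconnected mesh, $\alpha\to 0$) raises an informative error.
* Edge ordering in $M$ is lexicographic with $-1$ at the smaller index;
  any consistent convention gives the same cost.
* The reverse-correspondence subsample is fixed per frame (it depends only
  on the target); reverse nearest neighbors are recomputed every inner
  iteration. Subsample selection visits vertices in lexicographic
  coordinate order, so it is reproducible and storage-order independent.
* Normalization maps the joint bounding box to `[0,1]^3` by default; a
  symmetric `[-1,1]^3` cube is selectable
  (`normalize_to_unit_cube(cube = "symmetric")`) but changes only the
  scale convention, not the registration behavior at matched settings.
* Correspondence pruning (dropping matches to target-boundary vertices or
  normal-incompatible matches, a feature of the ancestor algorithm this
  method descends from) is available behind
  `registration_config(prune_borders =, prune_normals =)` but is off by
  default: the four-term cost above does not include it.

## Cycle tracking

Each frame transition runs two passes. Pass 1 registers the chamber
submesh (everything except the LAA interior; the ostium ring included)
onto the frame's chamber target, with boundary-ring vertices landmarked at
their frame-0 positions ("non-moving" vessel cuts). Pass 2 registers the
LAA submesh onto the frame's LAA target with the ostium ring landmarked at
its pass-1 position, the LAA stiffness schedule, and the bi-directional
term. Merged output copies the ostium from pass 1.

Chains run forward 0% → 5% → … → 50% RR and backward 0% → 95% → … → 50% RR,
each step seeding the next registration with the previous result; the 50%
frame is the unweighted per-vertex mean of the two chains ("interpolated"
admits several readings; the mean is symmetric and
reproduces either chain when they agree).

## Smoothing, volumes, flows

Tracked trajectories are smoothed per vertex and coordinate with cubic
B-splines with 15 interior knots, uniformly spaced over one cycle. The fit
is made periodic by sample extension: frame 0 is repeated at $t=T$ and
three wrapped frames are padded on each side of the seam. Without the
padding the fit has a C0 kink at the cycle seam that differentiates into
~100 ml/s spurious flow spikes. The spline is evaluable at arbitrary
times; the export grid is 0.5 ms.

Volumes are computed every 5 ms by the divergence theorem,
$V=\frac{1}{6}\left|\sum_f v_1\cdot(v_2\times v_3)\right|$, on the capped
region submesh: the LV is closed by fan caps at the mitral annulus (and any
vessel cut), the LAA at the ostium. Caps use centroid fans — the loops are
near-planar cuts, where the fan is volume-exact in the planar limit. MV
flow is the time derivative of LV volume (cycle-wrapped central
differences): volume *increase* is transmitral inflow — diastolic filling
raises LV volume, and the inflow-positive convention yields the familiar
positive E/A waves. The unclamped derivative is always kept in the `raw`
attribute. LAA outflow is $-\,dV_{LAA}/dt$ where $V_{LAA}(t)$ is
the capped LAA volume clipped at a *static* orifice plane — the
least-squares plane through the frame-0 ostium ring — matching the static
plane used for comparison against 4D flow MRI.

### Flow metrics and their detector

Diastole is located on the raw derivative as the contiguous cycle-wrapped
interval above $-10\%$ of the maximum that contains the global inflow peak,
end-trimmed to non-negative samples. The tolerance is needed because a
15-knot spline of a curve with sharp E/A waves rings at the $\pm30$ ml/s
level around diastasis even for perfectly tracked input; a tight (1%) band
splits diastole in two. Within the interval, the E peak is the first and
the A peak the last local maximum at or above 10% of the curve maximum;
they must be distinct, at least 5% of the cycle apart, and separated by a
local minimum — otherwise the package refuses with "E/A not separable"
rather than guessing. The peak time span is $t_A - t_E$ and Ef/Af is the
peak-rate ratio.

Stroke volume is the *net* integral of the raw derivative over diastole,
i.e. the diastolic volume rise. Integrating the positive-clamped curve
instead would add the absolute smoothing ripple (about 3 ml at 15 knots
even with perfect tracking) and systematically overestimate; the net
integral satisfies volume conservation against EDV−ESV to well under 1%.

## The synthetic phantom

The generator builds a deforming left heart with analytic ground truth:

* **Geometry.** LV and LA are truncated ellipsoids of revolution sharing a
  fixed mitral annulus ring; the LA roof has an open pulmonary-vein cut
  (the boundary ring). An ostium patch carved from the LA wall borders a
  tapered LAA sack (45 mm long, tapering to 70% radius) whose perimeter is
  the shared ostium ring. The source is meshed at 4 mm (LAA axially at
  1 mm — the stiff LAA schedule needs a dense transform sampling along the
  contraction gradient); targets are *independently* meshed ~2.5× finer
  with a rotated angular grid, emulating the density contrast between a
  regularized source mesh and CT threshold isosurfaces, and are never
  index-aligned with the source.
* **Dynamics.** LV volume follows EDV − ejection + E-wave + A-wave, built
  from $C^\infty$ compact-support sigmoidal pulses, so truth flow curves
  are closed-form. Defaults: EDV 120 ml, ESV 50 ml (stroke volume 70 ml),
  E at 55% RR and A at 85% RR with a 70/30 volume split and half-support
  10% RR (support 20% RR; a 10% full support would produce ~900 ml/s peak
  inflow, outside the physiologic range). The LAA empties from 8 to 3 ml
  with a cosine-power dip (power 4) centered at 90% RR — a rapid late
  contraction that only one or two frames catch near its minimum, which is
  the clinically hard case. The LA varies reciprocally with LV filling.
* **Exactness.** Motion is a linear displacement family per region (zero
  at the annulus, ostium and boundary rings); the per-frame family
  parameter is root-solved so the *meshed* capped LV and LAA volumes equal
  the analytic curves to solver tolerance. Green volume-recovery tests
  therefore measure registration + smoothing error only, not meshing error.
* **What it does not emulate.** Trabeculation, papillary muscles,
  pulmonary-vein anatomy, valve leaflets, image noise and segmentation
  artifacts (targets can be jittered with seeded Gaussian noise, which is a
  crude stand-in), and through-plane motion of a real annulus. A green
  end-to-end test says the algorithmic chain recovers prescribed smooth
  wall motion; it does not certify accuracy on patient CT.

## Known limitations

* **Closest-point matching is vertex-to-vertex**; with a coarse target,
  accuracy floors at the target vertex spacing. The phantom generates dense targets for this reason.
* **LAA refill lags.** With the prescribed LAA schedule (final stiffness
  10) and vertex matching, *expansion* steps of the LAA recover only
  ~30–50% of the per-step volume change at equilibrium, while contraction
  steps recover ~100%: the expanding source sits inside the target, where
  lateral closest-point residuals cancel and the remaining inward offset is
  invisible to the correspondence field. Through the chain this appears as
  a ~1-frame lag of the refill branch, and the LAA peak-outflow magnitude
  is systematically *underestimated* (the peak time is preserved) — the
  same sign of bias that CT-based flow estimates of this kind show when
  compared against 4D flow MRI. The
  chamber passes (final stiffness 1, gentler curvature) do not show this
  behavior at a measurable level.
* The B-spline smoother with the prescribed 15 knots rings at sharp flow
  transients (~6% of the E peak); peak *rates* are accordingly ~5–10%
  high at the E wave. Volume-derived quantities (stroke volume, timing)
  are insensitive to it with the net-integral definitions above.
* The orifice-plane clip assumes the ostium stays near the frame-0 plane;
  `laa_flow_curve()` validates this and refuses otherwise.
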