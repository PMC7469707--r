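---
title: "Discrete element analysis of joint contact: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete element analysis of joint contact: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edem)
```

## The model

The package estimates contact pressure in an articular joint — the motivating
application is the tibiotalar (ankle) joint during the stance phase of gait —
using a discrete element (rigid-body spring) idealisation. Both bones are
rigid triangulated surfaces; the cartilage between them is an elastic
foundation: a mattress of independent compressive springs with no shear
coupling between neighbours. One spring is anchored at the centroid of each
talar triangle and directed along the triangle normal; its far end is found
by intersecting that normal ray with the tibial surface, so the spring length
$h_i$ is the local articular gap. Springs whose length exceeds a threshold
$h_T$ are removed from the computational domain; the survivors form the
*nominal* contact region.

Each spring is a confined elastic column of cartilage. Its stiffness is

$$k_i = s(\nu)\, E \, \frac{A_i}{h_i}, \qquad
  s(\nu) = \frac{1-\nu}{(1-2\nu)(1+\nu)},$$

with $E$ and $\nu$ the cartilage Young's modulus and Poisson ratio, $A_i$ the
triangle area and $h_i$ the *current* gap. Because $h_i$ is re-measured at
every time point, stiffness rises as the gap closes: this is the
strain-dependent (nonlinear) part of the model.

Two solution modes share one equilibrium core:

* **DEM** (classical): at every time point the moving bone (talus) is held at
  its reference position; the solve finds a virtual translation $u$ such that
  the spring forces $f_i = k_i\, (n_i \cdot u)$ balance the applied joint
  contact force. The displacement is used only to evaluate forces.
* **EDEM** (extended): the talus actually translates. The equilibrium
  translation increment of frame $t$ moves the bone, and each active spring
  stores its equilibrium force as a *push-back* force $f^{i}_{t-1}$, so the
  next frame solves $f_i = k_i\,(n_i \cdot u) + f^{i}_{t-1}$. When the
  applied load falls, the stored compression drives the talus back toward its
  original pose — the memory that distinguishes EDEM from a sequence of
  independent static solves. At $t=0$ (zero state) the two modes coincide
  exactly.

Equilibrium is translation-only (talus rotations are pinned to zero), so the
balance is three equations in three unknowns on the current active set $S$:

$$\sum_{i\in S}\left[k_i (n_i\cdot u) + f^{i}_{t-1}\right] n_i
  \;-\; F_{\mathrm{lig}}(u_{\mathrm{cum}}+u) \;=\; F_{\mathrm{applied}}.$$

Sign conventions are pinned in one place (the solver header): $n_i$ points
from talus to tibia, positive $f_i$ is compression pushing the talus away
from the tibia, and $F_{\mathrm{lig}}$ is the ligament force acting on the
talus. Springs cannot pull: after each solve, springs with $f_i \le 0$ are
released and the solve repeats on the reduced set until only compressed
springs remain — the *active* contact region. Contact pressure on a triangle
is its spring force divided by its area; active area is the summed area of
the active triangles.

Four ligament bundles (anterior/posterior tibiotalar, anterior/posterior
talofibular) are tension-only linear fibres with tension
$T = (E_{\mathrm{lig}} A / L_0)\max(\Delta L, 0)$, rest lengths captured at
the reference pose with no pre-strain.

## Parameters, units and defaults

Units are mm / N / MPa throughout (1 MPa = 1 N/mm²); angles are degrees at
interfaces and radians internally.

| parameter | default | meaning |
|---|---|---|
| `E_cartilage` | 10.35 MPa | cartilage Young's modulus; homogeneous over the joint |
| `nu` | 0.4247 | cartilage Poisson ratio; enters only through $s(\nu) \approx 2.68$ |
| `h_threshold` | 3.5 mm | spring length cut-off — twice a typical undeformed tibiotalar cartilage layer |
| `E_ligament` | 255 MPa | ligament Young's modulus |
| `fibre_area`, `fibres_per_bundle` | 1 mm², 5 | ligament discretisation; not constrained by the source data, exposed in the configuration |

The cartilage modulus acts as a pure scale factor in a single force-controlled
DEM step: multiplying $E$ by $c$ leaves every spring force and pressure
unchanged and divides the displacement by $c$ (the package asserts this
homogeneity as a test invariant). Across an EDEM history the statement is only
approximate, because the displacement feeds back into the recast gaps; the
invariant is therefore asserted for the stateless single step only.

## The solver

For a fixed active set the balance is solved by Newton iteration: the 3×3
tangent is $K = \sum k_i n_i n_i^{\mathsf T} + K_{\mathrm{lig}}$, with
$K_{\mathrm{lig}}$ the material-plus-geometric tangent of the taut fibres.
Without ligaments the system is linear and one step is exact. Numerical
choices that matter:

* **Rank-deficient spring beds.** Parallel flat plates give $K$ of rank one.
  The solve uses an eigenvalue pseudo-inverse (cut-off $10^{-10}$ of the
  largest eigenvalue) and *errors* if the applied force has a component
  outside the range of $K$ — an under-constrained equilibrium, not a warning.
* **Tension-only kink.** A fibre exactly at its rest length contributes its
  material stiffness to the tangent (the taut-side subgradient), so a
  transverse load restrained only by ligaments sees the restraint at the
  first iteration. If all fibres momentarily fall slack mid-iteration, a
  damped (Levenberg-style) step keeps the Newton moving; a genuinely
  unbalanced load still fails the convergence check.
* **Release rule.** By default every non-compressed spring ($f_i \le 0$) is
  released per iteration (`all_tensile`); `most_tensile_only` releases one at
  a time for conservative descent. Released springs are never re-admitted
  within a time point; all springs become available again when the mattress
  is recast at the next one. Both rules give identical fixed points on the
  random systems in the test suite.
* **Full unloading.** When every spring releases, the solve is accepted as a
  lift-off equilibrium only if the remaining residual (applied force versus
  ligaments alone) meets the tolerance — first at the last computed
  displacement, then at the reference pose, then by a ligament-only damped
  Newton. This is what lets a congruent joint return exactly to its reference
  pose at the end of an unloading ramp: all spring forces cross zero
  simultaneously, and the released state is a valid equilibrium. The
  zero-load shortcut (return the zero solution without iterating) applies
  only when the stored forces and the ligament force are also zero —
  otherwise a zero-force frame must run the release iteration, or the talus
  would never move back.
* **Tolerances.** Residual tolerance defaults to
  $10^{-8}\max(1, \lVert F\rVert)$ N; the active-set iteration cap defaults
  to the initial nominal spring count (the set can only shrink, so this
  bounds the iteration); spring lengths below $10^{-3}$ mm raise an
  interpenetration error rather than clamping the $1/h$ stiffness.
* **Stiffness update.** `lagged` (default) evaluates $k_i$ from the gap at
  the start of the time point and holds it through the solve — lengths are
  updated between time steps, not within a solve. `within_step` recomputes
  $k_i$ from the deformed gap $h_i - n_i\cdot u$ each iteration for
  comparison; it stiffens the bed and yields slightly smaller displacements.
* **Stored-force bookkeeping.** Springs that leave the nominal region
  (absent or over-threshold after a recast) drop their stored force to zero:
  the push-back force is defined only for springs in the contact domain.
  Ligaments are evaluated at the current cumulative pose and carry no memory
  of their own; the springs carry the history.

## The stance pipeline

Each frame of a gait table (time or percent of stance, joint angle, 3-vector
joint contact force) is processed as: rotate the tibia (and the ligament
fixed anchors) from the reference pose to the frame angle about the joint
axis — absolute re-posing, not incremental, to avoid drift; recast, threshold
and stiffen the mattress from the current talus pose; apply the frame force;
solve; and (EDEM only) translate the talus and carry the state. The joint
force is a point load at the talus centroid, but with translation-only
equilibrium only the force vector enters the balance; the application point
is recorded and no torque equation is formed. The joint axis itself is the
axis of the least-squares cylinder fitted to the talar articular surface.

The cylinder fit runs Gauss–Newton (five parameters: in-plane axis offset and
tilt, radius) on the radial residuals of the triangle centroids — centroids
rather than vertices, since centroids are the anchors of the contact springs.
Initialisation uses the smallest eigenvector of the triangle-normal
covariance: the normals of a cylindrical patch span the plane perpendicular
to its axis, which identifies the axis direction robustly even for short,
wide patches where the centroid principal axis is ambiguous. A planar patch
(two near-zero normal-covariance eigenvalues) has no defined axis and is
rejected.

Clinical force columns (medial/lateral, posterior/anterior,
superior/inferior) are mapped onto the anatomical frame +x anterior / +y
superior / +z lateral by a configurable 3×3 matrix, defaulting to
"first-named direction is positive" (medial = −z, posterior = −x,
superior = +y). The mapping is configuration, not code, because sign
conventions for reported joint-reaction components vary between motion
laboratories.

## Synthetic fixtures: what they emulate, and what they do not

The generator produces joint geometries with known analytic properties:

* `flat_congruent` — parallel plates, uniform gap: the closed-form oracle
  (uniform pressure $F/A$, displacement $Fh/(s(\nu)EA)$).
* `cylinder_congruent` — concentric cylinder sectors, constant radial gap: a
  trochlea-like hinge whose generating axis the cylinder fit must recover.
* `cylinder_incongruent` — tibial radius exceeding talar radius + gap, so
  the gap grows away from the apex: graded engagement, a threshold-bounded
  nominal region, and a contact patch that grows as the talus settles.
* `flat_with_depressions` — local tibial depressions pushing the gap above
  the threshold: persistently inactive regions surrounded by load-bearing
  contact, the mechanism behind central inactive zones seen on real tibial
  plafonds.

Default dimensions were chosen once to sit at the anatomical scale of an
adult ankle: talar radius 20 mm, 90° arc, 20 mm axis length (articular area
≈ 6.3 cm², the same order as a real tibiotalar facet), gaps of 1.5–2.5 mm
against the 3.5 mm threshold, and a default resolution of ~800 triangles so
that the whole test suite runs in seconds; the convergence study refines to
~32 000 triangles, bracketing the mesh density a subject-specific model
would use. Load profiles are a half-sine ramp peaking at 2000 N (about 3×
body weight, the scale of the ankle joint reaction in walking) or a
piecewise-linear interpolation of the packaged seven-row stance table whose
peak superior force is 4078.26 N at 78% of stance.

What the fixtures deliberately do **not** reproduce: real talar topography
(no shape model), cartilage thickness maps from imaging, anatomically placed
ligament footprints, or out-of-plane joint forces coupled to bone rotation.
Passing tests on these fixtures therefore validate the *mechanics* — force
balance, tension release, state memory, threshold behaviour, convergence —
not the subject-specific pressure magnitudes of any individual joint, which
depend on geometry the fixtures intentionally idealise.

## Sensitivity analysis

`run_sensitivity_grid()` re-runs the full stance over a uniform grid of the
length threshold ($h_T \in [2.5, 4.5]$ mm) and the ligament modulus
($E_{\mathrm{lig}} \in [200, 350]$ MPa), recording the maximum over frames
of the peak contact pressure as the response. Grid cells are independent
(results are identical whatever the evaluation order, which the tests verify
by re-evaluating isolated cells), and a failing cell is recorded with its
reason rather than aborting the grid. Gradients are central differences in
the interior and one-sided at the edges; missing cells mask themselves and
their finite-difference neighbours. On the synthetic fixtures the threshold
dominates the response and the ligament modulus is secondary — the same
ordering reported for subject-specific geometry — but the printed
percentage magnitudes of any particular subject are not recoverable on
idealised fixtures, and the package makes no claim to them.

## Known limitations

* Cartilage is elastic: no viscoelastic or biphasic behaviour, appropriate
  for gait-scale loading rates but not for creep or stress-relaxation
  questions.
* The talus only translates; rotations are pinned and no torque balance is
  formed.
* Springs are independent — no shear coupling, so pressure gradients across
  neighbouring triangles are unregularised.
* The two articular cartilage layers are lumped into a single spring per
  triangle pair; per-point thickness from imaging is not used.
* Ligaments are linear tension-only fibres without toe region, wrapping, or
  a mobile fibula.
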