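---
title: "Poro-viscoelastic modelling of an idealised decompressive craniectomy"
author: "dcpve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poro-viscoelastic modelling of an idealised decompressive craniectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Decompressive craniectomy (DC) relieves raised intracranial pressure by
removing part of the skull, letting the brain bulge through the opening.  The
mechanical strain imposed on the tissue by that herniation is a suspected
source of secondary damage, and it cannot be measured clinically at the time
of surgery.  A tractable way to study it is an idealised bench model: a soft
hydrogel cylinder confined by rigid walls, loaded by a rigid platen that
contains a circular "craniectomy" opening of radius $a_c$ with an edge fillet
of radius $R_f$.  The platen descends a few millimetres and holds; the gel
bulges through the opening, the load relaxes, and ink markers on a cut face
let the strain field be imaged.

`dcpve` implements the complete computational side of such a study:

1. **Material model** — closed-form poro-viscoelastic (PVE) constitutive
   functions: Prony-series stress relaxation with ramp correction, and
   Terzaghi consolidation.
2. **Characterization** — nonlinear least-squares identification of the PVE
   parameters from unconfined (visco-elastic) and confined (poro-elastic)
   compression records.
3. **FE solver** — an axisymmetric quasi-static mixed displacement–pressure
   finite-element model of Biot consolidation with Prony solid relaxation on
   the idealised craniectomy geometry.
4. **Strain imaging** — marker detection, trajectory linking, polynomial
   smoothing, Delaunay triangulation and constant-strain-triangle
   Green–Lagrange strain fields from image stacks.
5. **Synthetic data** — seeded generators for every input, with ground truth,
   so each stage can be validated by parameter/field recovery.
6. **Pipeline** — load normalisation, parametric sweeps, phase decomposition
   and curve comparison, plus a thin subcommand CLI (`inst/cli/dcpve`).

## The material model

The solid skeleton relaxes according to a Prony series applied equally to the
shear and bulk moduli (the $g_i = k_i$ assumption), so one dimensionless
relaxation function scales the whole elastic stiffness:

$$g_R(t) = 1 - \sum_i g_i\left(1 - e^{-t/\tau_i}\right),
  \qquad g_i \in (0,1),\ \textstyle\sum_i g_i < 1 .$$

For a displacement-controlled unconfined compression test ramped linearly
over $t_r$ and held, the Boltzmann hereditary integral gives the post-ramp
force in closed form,

$$F(t) = \frac{\pi d^2}{4h}\, u_{max} \Big[C_0 + \sum_i C_i R_i\,
  e^{-(t-t_r)/\tau_i}\Big], \qquad
  R_i = \frac{\tau_i}{t_r}\left(e^{t_r/\tau_i} - 1\right),$$

where $R_i \ge 1$ is the ramp-correction factor ($R_i \to 1$ for an
instantaneous ramp).  With moduli in kPa and lengths in mm the force comes
out in mN; the package uses the mm/s/N unit system throughout, converting
kPa to N/mm² internally, to avoid silent magnitude errors.

The poro-elastic side is characterised by the instantaneous Young's modulus
$E$, drained Poisson's ratio $\nu$, undrained ratio $\nu_u$ (fixed at $1/2$:
incompressible constituents) and hydraulic conductivity $k$ (mm/s).  A
confined, top-drained sample under constant load settles following the
Terzaghi solution

$$U(T) = 1 - \sum_m \frac{2}{M_m^2} e^{-M_m^2 T},\quad
  M_m = \frac{\pi}{2}(2m+1),\quad T = \frac{c\,t}{h^2},\qquad
  c = \frac{2\,\kappa\,G\,(1-\nu)}{1-2\nu},\ \kappa = k/\gamma_w .$$

This $c$ is the incompressible-constituent limit ($B = 1$, $\nu_u = 1/2$) of
the general consolidation coefficient, and matches the one-dimensional
oedometric form $c = \kappa\,E_{oed}$.  The 200-term default truncation is
exact to double precision for $T \ge 10^{-4}$; below that the package uses
the early-time expansion $U \approx 2\sqrt{T/\pi}$, whose finite-layer
correction is $O(e^{-1/4T})$ and far below machine precision there.

## Parameter identification

`fit_unconfined()` fits $\{C_0, C_i, \tau_i\}$ (three terms by default) to
the hold phase ($t \ge t_r$; the closed form above is a post-ramp model) by
Levenberg–Marquardt on log-parameters, which enforces positivity.  Prony
fitting is notoriously multi-modal, so the fit is multi-started: one
deterministic start with log-spaced time constants and further seeded
restarts with log-uniform $\tau$ draws over $[0.1, 1000]$ s.  A very small
ridge on the Prony amplitudes ($10^{-3}$ of the force scale, relative bias
$O(10^{-9})$) resolves the degeneracy of near-constant records, which are
otherwise fit equally well by $C_0$ or by a term with $\tau \to \infty$.
`fit_confined()` fits $\{c, s_\infty\}$ in
$s(t) = s_\infty U(c\,t/h^2)$ the same way, and inverts the consolidation
coefficient for $k$ when $G$ and $\nu$ are supplied.  $\nu$ itself is a
configuration input: it is not identifiable from these two tests alone, and
no third test is modelled.

The recovery tests establish what these fits can and cannot do: noise-free
synthetic curves are recovered essentially exactly; at 1% force noise the
median error over 20 seeded replicates stays within a few percent for the
moduli and somewhat more for the time constants, with the smallest, slowest
Prony term always the hardest.  Recovery error grows monotonically with the
noise level.

## The finite-element model

The domain is the $(r, z)$ rectangle $[0, R] \times [0, H]$, meshed by a
tensor product of graded one-dimensional subdivisions refined towards the
opening edge $(a_c, H)$: element size at most `fine` within a band around
the edge (at least $2R_f$, with a floor of six fine elements so meshes stay
comparable across a fillet sweep), growing geometrically to `far`.
Displacements use 9-node biquadratic elements, pore pressure 4-node bilinear
elements on the corner grid — a Taylor–Hood pair, inf-sup stable for the
mixed Biot problem (requesting equal-order interpolation only earns a
warning).  Reduced-integration hybrid element technology of commercial codes
is not replicated.

Because the same spectrum scales all moduli, the viscoelastic
internal-variable update collapses to scalar factors on one stiffness
matrix: with $\beta_i = (\tau_i/\Delta t)(1 - e^{-\Delta t/\tau_i})$, the
step solves

$$\Big(g_\infty + \sum_i g_i\beta_i\Big) K_0\,u^{n+1} - Q\,p^{n+1} = f +
  \sum_i g_i \beta_i K_0 u^{n} - \sum_i e^{-\Delta t/\tau_i} H_i^{n},$$

coupled to backward-Euler Biot continuity
$Q^{\!\top}(u^{n+1}-u^n) + \Delta t\, H p^{n+1} = 0$, with the history
vectors recurring as
$H_i^{n+1} = e^{-\Delta t/\tau_i} H_i^n + g_i\beta_i K_0 (u^{n+1}-u^n)$.
This is algebraically identical to the per-Gauss-point exponential update
but carries the history as nodal force vectors.  Time steps are dense during
the ramp (at least 20) and grow geometrically through the hold.

Boundary conditions: $u_r = 0$ on the axis and outer wall, $u_z = 0$ on the
bottom.  The platen is replaced by prescribed vertical displacement with
free radial slip (frictionless rigid contact without lift-off).  The fillet
is not meshed as curved geometry; instead the prescribed displacement is
relieved by the quarter-round edge profile,
$u_z(r, t) = -\max(u_p(t) - \delta(r),\, 0)$ with
$\delta(r) = R_f - \sqrt{R_f^2 - (a_c + R_f - r)^2}$ in the band, so the
contact radius grows as the platen descends — which is how a rounded rigid
edge actually loads a surface.  A plain cosine blend of width $R_f$ was
tried first and rejected: it rescales the *whole* band displacement, which
effectively moves the opening radius with $R_f$ and changes the relaxed load
fraction, destroying the fillet-invariance of the normalised response that
the offset profile (and the physical fillet) exhibits.  A fixed 1 mm cosine
taper at $r = a_c$ removes the residual displacement discontinuity a small
fillet leaves at the opening edge (a flat-punch singularity whose discrete
reaction does not converge under refinement).

Pore pressure is fixed to zero on the permeable external boundaries — outer
wall, bottom, and the part of the top surface the platen never touches —
but never under the platen itself: a rigid platen blocks flow regardless of
the boundary-condition mode.  `pore_bc = "impermeable"` removes all pressure
constraints.  The platen load is evaluated as the sum of discrete reaction
forces at the constrained vertical dofs (the weak-form equivalent of
$-\int \sigma_{zz}\, 2\pi r\, dr$), and the boundary outflow as the
continuity-equation residual at the pressure-constrained nodes, which makes
the discrete mass balance exact: in the verification column the cumulative
outflow equals the settled volume to round-off.

Kinematics are small-strain throughout, although the bulge through the
opening reaches displacement amplitudes comparable to the domain size
(volume conservation amplifies the platen displacement by roughly
$(R^2 - a_c^2)/a_c^2$).  This is a deliberate simplification: the linear
model keeps every verification problem exactly solvable, at the cost of
treating the large bulge displacements only approximately.  Unilateral
contact with lift-off, 3-D head geometry and finite-strain constitutive
laws are out of scope.

## Verification strategy

Three analytic anchors pin the solver down.  (i) *Patch test*: a full-width
platen on a laterally confined, effectively drained column must produce a
uniform $\varepsilon_{zz} = -u/h$; the Taylor–Hood space contains this
solution, so it is reproduced to solver tolerance on any graded mesh.
(ii) *Terzaghi column*: with the Prony spectrum empty, a top-drained column
under constant traction must settle as $s_\infty U(ct/h^2)$; the relative
$L_2$ mismatch at the demonstration discretisation (30 × 2 elements, 60
log-spaced backward-Euler steps) is well under 2% and halves as the step
count doubles — the residual error is temporal, the drained limit being
exact in space.  (iii) *Drained viscoelastic form*: with conductivity large
enough that pressures vanish, the full-width-platen load history must be a
ramp-corrected Prony relaxation; fitting it with `fit_unconfined()` recovers
the generating time constants and $R^2 > 0.999$.

## Demonstration conditions

No measured gel or rig parameters ship with the package.  Instead it
provides one self-consistent set of demonstration values, chosen once as
plausible bench-rig numbers and used by `dc_demo_material()` /
`dc_demo_config()`:

| quantity | value | why |
|---|---|---|
| cylinder radius × height | 75 × 50 mm | desk-scale semi-cylindrical rig |
| opening radius $a_c$ | 20–30 mm (baseline 25) | DC-like opening sizes |
| fillet radius $R_f$ | 1.5–4.5 mm (baseline 3) | machining-scale edge rounding, an order below $a_c$ |
| platen displacement | 5 mm at 1 mm/s | surgical-speed loading |
| hold | 600 s | comparable to the opening-scale consolidation time $a_c^2/c$ |
| $E$, $\nu$ | 20 kPa, 0.35 | weak gelatin stiffness range |
| Prony $g$, $\tau$ | (0.30, 0.15), (1, 10) s | moderate relaxation, decade-spaced |
| $k$ | $2\times10^{-5}$ mm/s | hydrogel conductivity; gives $c \approx 0.065$ mm²/s |
| mesh fine / far | 1.5 / 7 mm | resolves the edge band; keeps a run at seconds |

These are *demonstration* values, not measurements of any physical gel.
With them the model reproduces the qualitative findings the package's
acceptance tests check: peak load falls monotonically as $a_c$ grows while
the peak-normalised curves share an early master curve and diverge late;
the fillet lowers the peak load slightly and the edge shear strain strongly,
while leaving the normalised shape invariant to under 1%; impermeable pore
boundaries give a several-fold larger centreline bulge and late-time load
than permeable ones; and the normalised load shows two relaxation phases,
superposing on the visco-elastic-only curve before ~15 s (1.5× the longest
Prony time constant) and on the poro-elastic consolidation shape late in
the hold.  Early-phase superposition is limited by consolidation's
$\sqrt{ct}$ onset at the drained boundaries — there is no true poro-elastic
"delay" — which is why the early window is defined relative to the visco
spectrum rather than by an absolute time.

## Strain imaging

Markers are dark ink dots on a bright gel face.  Detection thresholds the
image, labels connected components (EBImage), filters by area and computes a
darkness-weighted centroid over the component's bounding box dilated by two
pixels, weighted against the background level — thresholding alone clips
partially covered edge pixels asymmetrically and pixel-locks the centroid at
the 0.05 px level, which the dilated weighting reduces several-fold.
Linking is mutual-nearest-neighbour within `max_disp` per frame (conflicts
resolved by distance, ties by index, suspended tracks surviving `memory`
frames), a deliberately simple variant of standard particle tracking that is
adequate for the sparse, slowly moving lattices of this application and easy
to verify.  Tracks present in fewer than `min_fraction` of frames (default
0.5; configurable) are discarded; survivors are fitted with second-order
polynomials in time per coordinate, which both smooths and interpolates
gaps.  The reference (first-frame) positions are Delaunay-triangulated
(`deldir`); each triangle is a constant-strain element whose deformation
gradient gives the Green–Lagrange tensor $E = (F^\top F - I)/2$ — exactly
objective under rigid rotations, which the tests check to $10^{-9}$ — with
the small-strain tensor as an option.  Sliver triangles from nearly
collinear boundary markers are flagged invalid by an area *and* a shape
quality threshold ($4\sqrt{3}\,\mathrm{area}/\sum \mathrm{edge}^2$), since
they amplify sub-pixel centroid noise into arbitrarily large strains.

The synthetic image generator renders anti-aliased disks displaced by a
known field (affine, simple shear, or a Gaussian bulge mimicking the
herniation profile), ramped linearly over frames like a constant-speed
platen, plus i.i.d. Gaussian noise.  What recovery on these stacks shows is
sub-pixel-level accuracy of the whole chain on smooth fields with
well-separated markers; what it does not show is robustness to marker
dropout, uneven illumination, or optical distortion, none of which the
generator emulates.  One real limitation is reproduced deliberately: a
marker grid coarser than a strain feature underestimates its peak, so the
acceptance suite checks that a coarse lattice recovers a smaller bulge-peak
shear than a fine one.

## Numerical choices and degenerate inputs

* Terzaghi series: 200 terms, early-time expansion below $T = 10^{-4}$.
* NLS fits: log-parameterised, clamped to $e^{\pm 20}$, capped exponents
  inside the model so Levenberg–Marquardt excursions stay finite;
  non-convergence of every restart is a hard error naming the restart count.
* FE time grid: ≥ 20 ramp steps, geometric hold steps (factor 1.18); the
  system matrix is refactorised only when the step size changes.
* Degenerate geometry: $a_c = 0$ is allowed and means a full-width platen
  (needed for patch tests and column verification); meshes that cannot put
  four elements across the opening are rejected.
* Strain sampling lines must be axis-aligned and inside the domain; on the
  axis the hoop term $u_r/r$ is evaluated just off $r = 0$.
* Ties in track linking are broken by marker index, deterministically.

## Reproducibility

Every generator is a pure function of its parameters and an integer seed;
`scripts/acceptance.R --seed S --out f.json` recomputes the package's
headline quantities from scratch.  The FE results are deterministic given a
configuration; the stochastic quantities (noisy-recovery medians, imaging
errors) vary mildly with the seed, which is exactly what they are for.
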