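---
title: "Methods: fibril-reinforced poroelastic analysis of focal cartilage defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibril-reinforced poroelastic analysis of focal cartilage defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cartimech)
```

`cartimech` quantifies the mechanical environment around a focal,
partial-thickness cartilage defect in an idealized tibial compartment over
the stance phase of gait. This vignette is the package's own account of the
science: the constitutive and field models, the discretization, the
synthetic study conditions and why they were chosen, and what the results
do and do not say about real joints.

## The tissue model

Articular cartilage is treated as a biphasic (poroelastic) continuum: an
intrinsically incompressible interstitial fluid percolating through a
porous solid skeleton. The skeleton is *fibril-reinforced*: a soft,
compressible Neo-Hookean ground matrix (proteoglycans) carries compression,
while tension-only collagen fibrils carry tension. The effective Cauchy
stress at a material point is

$$\sigma_\mathrm{eff} \;=\; \sigma_\mathrm{matrix}(\mathbf F)
  \;+\; \sum_i \rho_i\,\sigma_f(\varepsilon_{f,i})\,\mathbf n_i \otimes \mathbf n_i,
  \qquad
  \sigma_\mathrm{total} \;=\; \sigma_\mathrm{eff} - p\,\mathbf I ,$$

with $p$ the pore pressure, $\mathbf n_i$ the current fibril direction and
$\varepsilon_{f,i} = \lambda_i - 1$ the fibril engineering strain (stretch
minus one). The fibril law is elastic and strain-stiffening,

$$\sigma_f(\varepsilon) = (E_0 + E_\varepsilon\,\varepsilon)\,\varepsilon
  \quad (\varepsilon > 0), \qquad \sigma_f = 0 \quad (\varepsilon \le 0).$$

Fibril viscoelasticity is deliberately omitted: the failure metrics this
package computes are strain snapshots at the stance peaks, for which the
elastic backbone of the fibril-reinforced poroviscoelastic family is an
adequate and far cheaper surrogate. The interface would admit a
viscoelastic fibril extension without structural change.

One primary fibril family follows the Benninghoff arcade architecture:
parallel to the surface split lines in the superficial zone (normalized
depth $\le 0.15$), perpendicular to the bone in the deep zone (depth $\ge
0.70$), with a spherical linear interpolation between the two through the
middle zone (`arcade_direction()`). Thirteen secondary fibril directions,
fixed and approximately uniform on the sphere (a Fibonacci arrangement),
share the remaining fibril density and represent the unorganized part of
the network.

Default constants (`frpe_params()`): matrix modulus $E = 0.31$ MPa, Poisson
ratio $\nu = 0.42$, permeability $k = 2\times 10^{-3}$ mm$^4$/(N s), fibril
moduli $E_0 = 0.47$ MPa and $E_\varepsilon = 150$ MPa, primary fibril
density fraction 0.75. These are literature-informed values for human knee
cartilage; they are configurable (`inst/extdata/material_default.yaml`),
and none of the package's verification targets depends on their specific
magnitudes. Strain-dependent permeability is omitted because a single
stance cycle (0.6 s) involves negligible consolidation at these
permeabilities. The menisci, when generated, are linear elastic and
transversely isotropic about the circumferential fibre direction
(`meniscus_elasticity_tensor()`), attached through grounded horn springs of
350 N/mm total stiffness per horn.

## Discretization

The mixed displacement-pressure problem is discretized with equal-order
trilinear (hex8) interpolation and backward Euler in time. Equal-order
pairs are not inf-sup stable, so a polynomial pressure-projection
stabilization is added: per element, $\alpha \int_e (p - \bar p)(q - \bar
q)\,dV$ with $\alpha$ scaled by the inverse constrained modulus
(`stab_coeff`, default 0.25). The stabilization vanishes on element-mean
pressures, so global fluid mass is conserved exactly under sealed
conditions. Kinematics are geometrically linear; logarithmic (Hencky)
strain measures for reporting are computed from the displacement gradient,
so the reported principal strains are the finite-strain quantities used by
the failure limits. This small-strain equilibrium is the package's chosen
desk-scale compromise: at the strain levels the failure limits address
(up to ~30-40%), equilibrium geometry errors are second order, while a full
finite-strain solver would dominate the computational budget. The
material-point laws (`matrix_stress()`, `effective_stress()`) are
implemented fully finite-strain and objectivity-tested.

Contact with the femoral side uses a rigid analytic sphere. The "hard"
pressure-overclosure law is realized by a penalty (default 300 N/mm$^3$ of
tributary area), C$^1$-smoothed over a 0.05 mm penetration band - the
smoothing removes the force-gap kink that otherwise causes active-set
chatter. Contact forces act along the sphere normal, so the contact is
exactly frictionless. In force-controlled solves the indenter height is an
outer unknown: each height is solved displacement-controlled by a damped
(nonmonotone line-search) Newton iteration with adaptive height
continuation, and a bracketing secant / regula-falsi iteration drives the
axial contact resultant to the applied force within 0.3% (floored at 0.2%
of the protocol peak). This split is markedly more robust than carrying the
rigid-body height as a monolithic degree of freedom through penalty
contact. Submodels reuse the global indenter track and are therefore
displacement-controlled throughout.

Linear systems are symmetric quasi-definite after Dirichlet elimination and
are factorized by sparse LDL$^\top$ with a reused symbolic analysis (the
contact block sparsity is pre-seeded so the pattern never changes); a tiny
negative regularization on the pressure diagonal keeps the factorization
stable when every boundary is sealed and the pressure level is fixed only
through the coupling.

## The synthetic compartment

No subject geometry is distributed, so every analysis runs on a synthetic
compartment (`make_compartment()`): a spherical dish of radius 45 mm
carrying a cartilage layer whose thickness profile (base + linear gradient
+ central bump, kept within 1-4 mm) is realized exactly by offsetting the
surface along its local normal; the mesh is a layered hexahedral grid with
at least four element layers through the thickness, graded toward the
articular surface (depth fractions $(k/n_z)^{1.6}$) so the superficial
collagen zone is resolved by at least two layers at every element size. The 45 mm dish is an
*effective, meniscus-conformed* tibial surface: against the 35 mm indenter
it produces contact areas of roughly 100-200 mm$^2$ at stance loads, i.e.
physiological contact pressures of a few MPa. Split lines default to the
anterior-posterior direction with a configurable swirl.

Loading (`make_gait_protocol()`) is a smooth two-peak stance waveform - two
Gaussian bumps (width 6% stance) whose amplitudes are solved exactly so the
force at the configured peak times (15% and 85% of stance) equals the
configured multiples of body weight for a 71 kg subject. The default peak
multiples, 0.85 and 1.0 BW, are the share of the medial compartment load
transmitted through direct cartilage-cartilage contact: of the ~2.5-2.9 BW
total knee force at the peaks, roughly 60-75% passes through the medial
compartment and the menisci bypass about half of that around the
cartilage-cartilage contact. With this loading the intact model compresses
by roughly 10-20% at the contact centre, matching in vivo stance-phase
deformations. Early trials that pushed the full compartment load through
the bare cartilage contact produced >40% compressions and are not
physiological; this choice was made once, on that reasoning, and not
revisited.

Boundary conditions for scenario solves: the bone interface is fixed (tied
to rigid bone), the side faces of the meshed patch are rollers (in-plane
displacements fixed) approximating the lateral continuity of the
surrounding plateau, and the articular surface is free except for contact.
Fluid flow is sealed everywhere except through carved inner defect
surfaces, which are free-draining ($p = 0$) - a sealed-defect variant flips
only that set.

## Defects: carving, relocation, drainage

A defect is a closed footprint polygon in the tangent-plane chart at its
center plus a normalized penetration depth (depth divided by local
thickness). The defaults are the clinically measured 5.2 mm$^2$ and 63%.
Carving morphs the node columns of the layered mesh: the surface vertex of
a column inside the footprint moves to the defect floor along the local
normal and the column regrades beneath it, so the mesh stays conformal at
the rim with no remeshing. Each vertex carries a footprint *coverage*
fraction (16 sub-samples of its tributary cell), which smooths the walls
over one cell and makes the removed volume match the prism estimate
(area x depth fraction x thickness) to a few percent. Full-thickness
defects are carved to 99.5% so the remaining column keeps positive element
volumes.

Relocation transports the footprint polygon, unchanged, to the chart at the
target center and re-carves. Because the normalized-depth profile is a
function of chart coordinates, every relocated node sits at the projected
surface point minus its penetration fraction times the *local* thickness
along the local normal: the normalized depth profile and the projected
footprint area are conserved exactly, the absolute depth follows the local
thickness, and relocating back reproduces the original geometry to machine
precision. The chart is the orthographic tangent plane at the center
(transported by parallel transport, which for this shallow single patch
preserves the footprint orientation); the projected area is the polygon
area in that chart.

The intact-surface reconstruction over a defect (`fill_defect_surface()`)
is a discrete biharmonic (clamped thin-plate) fill on the structured
surface grid: two rings of surrounding vertices prescribe both position and
slope at the rim, so planes are restored exactly and a spherical cap is
restored to within a small fraction of its sagitta.

## Pipeline and submodeling

`run_scenario()` executes: fixtures, the intact global solve, then per
defect location the carve, the (optional) damaged global solve, and an
intact/damaged pair of submodels, ending in a `failure_report`. Submodels
are finer compartment patches (default 6 mm square at 0.3 mm elements)
centered on the defect; their cut boundaries follow displacements and pore
pressures interpolated from the global solution at every time step
(`submodel_bcs()`), their articular surface contacts the same indenter at
the global height track. By default both submodels are driven by the
*intact* global solution: at global element sizes (>= 1 mm) the 5.2 mm$^2$
defect is sub-element and its far-field influence is not resolvable, while
the carved global contact solve is fragile; `damaged_global = TRUE`
restores the full chain.

Failure analysis applies five literature limits - 7 MPa maximum principal
stress, 8% fibril strain, 30% maximum and -30% minimum principal
logarithmic strain, 32% maximum engineering shear strain (the largest minus
smallest principal strain) - with strict inequalities, so threshold
recovery by bisection is well defined. ROI maxima are taken over
integration points within 1 mm of the rim nodes, with distances measured in
the reference configuration. Exceedance intervals over stance interpolate
threshold crossings linearly between protocol samples. Intact-damaged
comparisons evaluate the intact measures at the damaged evaluation points
(directly when the meshes coincide, else by locating the points in the
intact mesh and interpolating nodal-projected fields) and report fold
changes with intact magnitudes below $10^{-4}$ masked out.

## Verification and study sizes

The package verifies itself at these problem sizes (chosen as sensible
desk-scale defaults):

- *Poroelastic oracle*: a 20-element confined-compression column under a
  ramp-hold surface pressure against the closed-form consolidation series
  (`consolidation_benchmark()`); settlement and mid-height pressure agree
  within 2% relative L2 over the hold phase.
- *Mesh convergence* (`convergence_study()`): the toy spherical-indentation
  scenario on a flat-profile 16 mm compartment (1.5 mm global elements,
  five-step ramp to the first-peak force), with a 3.6 mm submodel solved at
  0.3 mm and one uniform refinement (0.15 mm). Peak analyzed parameters
  (compressive principal strain, shear strain, maximum principal stress,
  fibril strain) are recovered at nodes by Gauss-point extrapolation,
  evaluated over the interior analysis window (1.2 mm clear of the cut
  boundary, whose interpolated conditions inherit gradient kinks from the
  coarse global field), and compared between levels against the 2% rule.
  At these sizes the shear, stress and fibril peaks meet the rule; the
  compressive peak converges more slowly and lands just above it,
  dominated by the in-plane contact-pressure discretization - the study
  reports this honestly rather than averaging it away.
- *Defect conservation*: relocation across a plateau whose thickness runs
  linearly from 1.5 to 3.5 mm preserves the 63% normalized depth and the
  5.2 mm$^2$ projected area.
- *Scenario regression*: a reduced defect scenario (12 mm compartment at
  1.5 mm, 7 protocol points, 4.5 mm submodel at 0.45 mm) exercises the full
  pipeline in about a minute; the acceptance-scale scenario uses 21
  protocol points and the 6 mm / 0.3 mm submodel.

## What passing these checks does and does not show

The synthetic world reproduces the *structure* of the real analysis -
curved cartilage with realistic thickness, depth-dependent collagen
architecture, biphasic load support over a two-peak stance, a clinically
sized defect with free-draining walls - and the package's qualitative
findings mirror the expected mechanics: the largest intact-damaged
differences appear at the second load peak, compressive and shear strains
concentrate at the defect rim with fold changes well above one, and the
compressive/shear criteria are the first to reach their limits as load
grows.

It does not reproduce patient-specific magnitudes. The geometry is
idealized; the femoral side is a rigid sphere; menisci are not in the
contact path (their geometric effect is folded into the effective dish
curvature, their mechanical bypass into the load share); there is no
osmotic swelling prestress; the solver is geometrically linear; and the
fibril constants are literature defaults rather than subject-calibrated
values. Strain peaks immediately at the rim of the sharp-walled synthetic
defect are mesh-sensitive in the way notch concentrations always are.
Absolute stresses and strains should therefore be read as
order-of-magnitude, and comparisons (fold changes, rankings across defect
locations, exceedance timing) as the meaningful outputs.
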