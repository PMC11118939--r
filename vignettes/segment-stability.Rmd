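---
title: "Modelling osteoporotic degeneration of an L2-L4 segment under compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling osteoporotic degeneration of an L2-L4 segment under compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lumbarfe)
```

# The problem

Osteoporosis thins the trabecular (cancellous) core of a vertebra and, in
advanced stages, disconnects it from the thin cortical shell; intervertebral
disc degeneration dehydrates and stiffens the disc tissues. `lumbarfe`
simulates how these two processes, alone and combined, change the compressive
load capacity, the disc deformation and the buckling stability of a
three-vertebra lumbar segment (L2-L4) compressed axially by an imposed
displacement of 2.5 mm at the top endplate with the base fixed.

Five scenarios ("grades") of age-related degeneration are swept:

| grade | trabecular density | cortical-trabecular bond | disc |
|---|---|---|---|
| 1 | 300 kg/m^3 | bonded | healthy |
| 2 | 100 | bonded | healthy |
| 3 | 100 | unbonded | healthy |
| 4 | 100 | bonded | degenerated |
| 5 | 100 | unbonded | degenerated |

# Synthetic geometry

No patient geometry is distributed with studies of this kind, so the geometry
module is a parametric stand-in built to the anatomy that such models report:
quasi-cylindrical vertebral bodies with an elliptic 40 mm x 33 mm
cross-section, 30 mm high, waisted by 10% at mid-height; a 0.5 mm cortical
shell on the lateral wall; 0.5 mm endplates; 10 mm discs whose nucleus
occupies 40% of the cross-section (the midpoint of the physiologic 30-50%
range); a single stiff posterior block standing in for the posterior
elements; and six ligament groups (ALL, PLL, CL, LF, ISS, SSL) as
tension-only links anchored on conventional landmarks of the simplified
geometry. All five components are meshed on one shared mapped elliptic grid,
so vertebra-disc interfaces share nodes by construction. The whole stack is
110 mm tall at defaults.

Two generator choices deserve emphasis:

* **Cortical shell nodes are separate nodes**, offset outward by half the
  shell thickness, tied node-to-node to the underlying solid surface. This
  realizes the bonded cortical-trabecular connection as force-distributed
  couplings that can be *removed* (the unbonded state) without touching the
  solid mesh. Ties adjacent to the endplates are always kept, so the load
  path through the endplates survives debonding.
* **A seeded geometric imperfection** (default amplitude 0.1% of the
  vertebral width, i.e. 0.04 mm) perturbs the lateral wall radially with a
  smooth random harmonic field. A perfectly symmetric discrete model never
  leaves the symmetric equilibrium path; the imperfection lets the physical
  bifurcation express itself numerically. Results quote the seed.

```{r}
mesh <- assemble_segment(element_size = 3)
mesh <- apply_imperfection(mesh, imperfection(amplitude = 0.04, seed = 1))
validate_mesh(mesh)
```

# Constitutive cards

All units are N-mm-MPa. The trabecular modulus follows the density power law
E_zz = 4730 rho^1.56 MPa (rho in g/cm^3): 723 MPa at the healthy 0.3 g/cm^3
and 130 MPa at the osteoporotic 0.1 g/cm^3, with transverse moduli
E_xx = E_yy = 0.1 E_zz and tabulated shear moduli. The cortical shell is
orthotropic (E_zz = 8000 MPa axially) and elastoplastic with a von Mises
yield stress of 64 MPa and linear isotropic hardening (the hardening modulus
is not part of the tabulated cards; the default is 5% of the axial modulus,
configurable). Endplates (E = 50 MPa, nu = 0.4) and the posterior block
(E = 3500 MPa, nu = 0.25) are isotropic. The healthy nucleus is nearly
incompressible (E = 1 MPa, nu = 0.4999); the degenerated nucleus is stiffer
and drains (E = 1.66 MPa, nu = 0.4). The annulus ground substance is
Neo-Hookean with C10 = mu0/2 and D = 2/K0 derived from (E, nu): the healthy
card derives from E = 1.4 MPa and the degenerated one from E = 6.3 MPa, both
at nu = 0.40, giving C10 = 0.25 / 1.13 MPa and D = 0.86 / 0.19 MPa^-1.

Three derivations required a documented decision:

* **Bulk-modulus relation.** The printed source form K0 = E/(3(1 + 2 nu))
  cannot reproduce the tabulated D values; the standard relation
  K0 = E/(3(1 - 2 nu)) reproduces both printed (C10, D) pairs exactly and is
  used. A dedicated test asserts the misprint.
* **Orthotropic Poisson convention.** Pairing the tabulated cross-plane
  ratios (nu_yz = nu_xz = 0.2) with the soft transverse moduli of trabecular
  bone makes the compliance indefinite (det < 0) -- no solver would accept
  the card. They are therefore paired with the axial modulus
  (S13 = -nu_xz/E_zz), the unique admissible reading; it changes nothing for
  isotropic cards.
* **Annulus volumetric coefficient.** Using the printed D values as the
  solver's volumetric stiffness gives a ground substance with a bulk modulus
  of 2.3 MPa (healthy) or 10.5 MPa (degenerated) -- about as compressible as
  it is shear-soft. Such an annulus swallows the volume displaced by the
  pressurized nucleus at negligible pressure: the simulated disc neither
  pressurizes nor bulges, the measured capacity collapses to a fraction of
  the reported range, and -- because the *degenerated* annulus card is
  volumetrically stiffer than the healthy one -- the degeneration ordering
  of the load capacity inverts. Hydrated ground substance is nearly
  incompressible, and the reported disc bulging is volume-consistent only
  under that treatment in *every* grade (healthy: 1.95 mm bulge at 0.7 mm
  height loss; degenerated: 2.34 mm at 0.97 mm). The solver card therefore
  derives D with nu_vol = 0.499 (the incompressibility value the source
  quotes for the healthy nucleus) in all grades, while C10 keeps the printed
  derivation; disc degeneration then acts through the printed nucleus card
  (nu 0.4999 to 0.4, E 1 to 1.66 MPa) and the printed annulus shear
  stiffening (C10 0.25 to 1.13 MPa). Set
  `default_material_library(..., annulus_volumetric_nu = 0.40)` to restore
  the fully printed cards.
* **Nucleus constitutive realization.** The nucleus works at pressures
  comparable to its shear modulus (p/mu near 1). A total-Lagrangian
  St.Venant-Kirchhoff solid is genuinely unstable under hydrostatic
  compression of that magnitude -- an artifact of the strain measure, not a
  property of a nearly incompressible gel (and absent from the hypoelastic
  "linear elastic" materials of commercial solvers). The nucleus card is
  therefore realized as a Neo-Hookean solid with the same small-strain
  moduli, which is stable under pressure; the pre-critical response is
  unchanged.

The annulus fibres are wound at +/-30 degrees to the disc circumference in
two concentric composite membrane layers (external 500 MPa, internal
300 MPa, 1.5 mm per layer, each a balanced laminate of both winding signs at
half thickness). They carry membrane stiffness only -- no bending -- and by
default resist both tension and compression, as composite shells do; a
tension-only fibre-family variant is available
(`fe_model(..., fibre_tension_only = TRUE)`).

# The finite-element engine

**Solids.** Eight-node trilinear hexahedra in a total-Lagrangian setting
(Green-Lagrange strain, second Piola-Kirchhoff stress), chosen over
quadratic bricks to keep the sweep desk-scale; the mesh-convergence harness
compensates. Orthotropic St.Venant-Kirchhoff cards are fully integrated
(2x2x2). Isotropic and Neo-Hookean cards use selective reduced integration:
the bulk/volumetric energy is sampled at the centroid only, which relieves
volumetric locking for the nearly incompressible nucleus and annulus.
Single-point bulk sampling leaves non-uniform dilatation ("volumetric
hourglass") modes restrained only by the shear modulus; for soft tissue with
K/mu of order 10^3 these become spurious low-energy modes that derail the
solution mid-path. A stabilization energy beta K/2 sum_g w_g
(trE_g - trE_c)^2 (beta = 0.05, capped at 50 mu) suppresses them; it vanishes
identically for uniform dilatation (so the patch test stays exact) and for
isochoric deformation (so locking relief is untouched).

**Shells.** The cortical wall uses flat 4-node shells: a bilinear membrane
with the full Green-Lagrange in-plane strain of all three displacement
components (so membrane stress stiffening and wall buckling are captured),
MITC4 Mindlin bending (no shear locking, no spurious modes), and a small
drilling-rotation penalty tied to the in-plane spin (invariant under rigid
rotation). Elastoplasticity is layered: five Gauss points through the
thickness, each with its own plane-stress von Mises backward-Euler return
map (the formulation accepts the orthotropic elasticity), so yielding starts
at the bending faces and membrane-bending coupling emerges consistently in
the plastic regime; transverse shear stays elastic. The reported von Mises
stress is the maximum over the layers (outer faces for elastic elements).
The fibre layers are separate membrane elements; their geometric stiffness
keeps only its tensile principal part, because a bending-free membrane under
compression has zero-energy wrinkling modes that would destabilize the
iteration matrix without changing any converged equilibrium.

**Ligaments.** Two-node links with engineering strain on the current length,
F = EA (L - L0)/L0 in tension and exactly zero force and tangent in
compression.

**Ties and constraints.** The node-to-node cortical ties are eliminated
(slave shell translations take the solid partner's dofs), keeping the system
positive definite and the reduced numbering contiguous; shell rotations stay
free. The base is fully clamped; the top endplate's axial translations are
driven to -2.5 mm t_bar, lateral translations free. Because every driven
node shares one axial displacement, the top face cannot tilt -- the segment
is axially guided, which is also why the slender-column verification problem
has critical load pi^2 E I / L^2.

**Solution.** Load stepping is displacement-controlled over 50 uniform
increments by default (pseudo-time resolution 0.02). Each increment starts
from a consistent-tangent predictor (linearized response to the prescribed
increment -- a naive jump of the driven dofs would crush the 0.5 mm endplate
layer), followed by Newton iterations to a residual of 1e-6 relative /
1e-8 N absolute, with a lazy backtracking line search. The sparse Cholesky
factorization (CHOLMOD, supernodal) is reused across iterations and
increments quasi-Newton style and refreshed whenever an iteration fails to
at least halve the residual. Past a critical point the tangent loses
definiteness; the iteration matrix is then regularized by a sticky
Marquardt-style shift proportional to each dof's own diagonal stiffness
(equilibria are unchanged -- iterations remain residual-driven).
Non-convergent increments are bisected up to four times; if the smallest
step still fails at a local fold (a short-wavelength snap of the soft disc
tissue), the driver leaps several increments ahead with an enlarged
iteration budget, which lands in the next smooth basin whenever the branch
continues. A failure after cutting and leaping returns the partial history
flagged as a loss of load-bearing capacity. Element inversion (det F below
0.05) also cuts the increment.

# Degeneration, stability and metrics

`apply_grade()` builds the grade's material library and, for unbonded
grades, deactivates the lateral-wall ties; the default scope debonds L3 only
(the vertebra whose failure the sweep focuses on), configurable to all
three. Plastic onset is the first increment with nonzero equivalent plastic
strain in the cortical shell; the onset stress is reported as the maximum
cortical von Mises at that increment and is typically below the uniaxial
yield stress because the shell stress state is multiaxial. Bifurcation is
detected from the lateral displacement history at probe point A (the
lateral-most wall node of L3 at mid-height): the response departs from
proportional growth when the incremental ratio du_x/dt_bar reverses sign or
jumps by a factor of 10 over the initial secant (the graphical construction
this replaces is not reproducible numerically; thresholds are configurable).
Post-buckling is unstable when the lateral magnitude subsequently shrinks
while the force plateaus or drops. `linearized_buckling()` solves
(K_e + lambda K_sigma) phi = 0 at a converged reference state via a
shift-and-invert Lanczos iteration on the Cholesky-transformed operator
(dense eigensolution below 800 dofs).

Deformation metrics follow fixed conventions: bulge is the maximum outward
radial displacement of a lateral node band relative to the region's mean
lateral translation; shear is the magnitude of the difference of mean
horizontal displacement between a disc's cranial and caudal interfaces;
shortening is the decrease of mean axial distance between a body's end
surfaces. All three are invariant under rigid translation. Percent changes
use `percent_more(value, baseline)` = 100 (value/baseline - 1); "X% smaller"
force statements are reproduced as `percent_more(F_reference, F_degraded)`.

The convergence harness reruns a model at decreasing element sizes and
applies the "no more than 5%" successive-difference rule to the tracked
summaries (reaction, von Mises maxima, wall bulge); exactly 5.0% passes.

# Problem sizes and what the tests show

The sweep runs at 3 mm elements (about 10,500 nodes, 29,000 reduced dofs)
and 50 increments -- deliberately desk-scale, roughly two orders of
magnitude below the meshes a commercial study would use. Unit tests verify
the machinery against closed forms (patch test to machine precision,
thin-plate bending within 2%, Euler buckling within 5%, finite-difference
energy-gradient consistency to 1e-4, tie-constraint equivalence to 1e-8);
the acceptance checks then ask for the *patterns* of the degeneration study
-- capacity ordering across grades, the physiologic 0.9-4.3 kN envelope,
relative deficits, bulge amplification, onset-vs-bifurcation ordering --
rather than digit-level agreement with a patient-specific model that cannot
be rebuilt from printed parameters.

What passing tests do **not** show: the generator's idealized geometry has
no lordotic curvature, no facet articulation and no real endplate geometry;
the posterior block is a placeholder with literature-style ligament anchor
areas; muscle forces and dynamic loading are excluded by design; and the
printed material set leaves the healthy annulus volumetric coefficient
internally inconsistent (resolved as described above). Conclusions about
real spines should rest on the directions and orderings this model
reproduces, not on its absolute forces.

```{r}
sweep <- run_grade_sweep(run_config(element_size = 3, n_increments = 50,
                                    seed = 1))
sweep$table
```
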