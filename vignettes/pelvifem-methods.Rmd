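---
title: "Methods: integrated pelvis-ring finite-element modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated pelvis-ring finite-element modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvifem)
```

`pelvifem` builds static finite-element models of the bony pelvis together
with its passive soft-tissue envelope and runs a two-model ablation protocol
that quantifies what that envelope contributes to pelvic load transfer.
This vignette is the package's own account of the model: the constitutive
and structural assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic phantom does and does not emulate,
and the numerical choices that a user extending the package should know
about.

## 1. Bone

Bone enters the model as two materials. **Cancellous bone** is
heterogeneous: each tetrahedron receives a Young's modulus mapped from the
CT intensity of the tissue it occupies, through apparent density,

$$\rho = \begin{cases} 1.9\times 10^{-3}\,\mathrm{Hu} + 0.105 & \mathrm{Hu} < 816\\
7.69\times 10^{-4}\,\mathrm{Hu} + 1.028 & \mathrm{Hu} \ge 816\end{cases}
\qquad [\mathrm{g/cm^3}]$$

$$E = 2017.3\,\rho^{2.46} \qquad [\mathrm{MPa}]$$

with Poisson ratio 0.2. The element's intensity is the mean over the voxel
centres contained in it (barycentric containment, inclusive boundaries at
a $10^{-12}$ tolerance); an element smaller than a voxel falls back to the
intensity of the voxel holding its centroid. The published piecewise density
fit is used as printed: its two branches disagree by about
$1.04\times10^{-4}\,\mathrm{g/cm^3}$ at the 816 HU break (we assign the
break itself to the upper branch), and for air and fat it extrapolates to
non-physical densities, so mapped densities are floored at
`rho_floor = 0.05` g/cm³ — without the floor, the power law would hand the
solver near-zero moduli and an ill-conditioned stiffness.

**Cortical bone** is deliberately not mapped: edge voxels blend bone and
surrounding tissue, so intensity-derived moduli are biased exactly where the
shell is thin. It is carried as a separate homogeneous material,
E = 17 GPa, ν = 0.26, on membrane (plane-stress) triangles of thickness
1.41 mm laid over the boundary faces of the bone regions, plus a
cortical-labelled outermost element layer in the volumetric mesh. The
membranes carry in-plane stiffness only; a bending formulation was left out
on purpose — in-plane action dominates the shell's contribution in a ring
loaded through its joints, and the membrane keeps the element simple and
verifiable. The thickness is a configurable scalar, so shell-sensitivity
studies need no code changes.

## 2. Cartilage

Joint cartilage can follow either of two published constitutive readings,
selected by `cartilage_family` in the run configuration:

* `"mooney_rivlin"` (default): the three-parameter hyperelastic energy
  $W = C_{10}(\bar I_1 - 3) + C_{01}(\bar I_2 - 3) +
  C_{11}(\bar I_1-3)(\bar I_2-3) + (J-1)^2/D_1$ with
  $C_{10}=0.1$, $C_{01}=0.45$, $C_{11}=1.67$ MPa and ν = 0.2. The source
  parameter set specifies ν but no bulk behaviour, so the volumetric term is
  the standard decoupled $(J-1)^2$ penalty with $D_1$ derived from ν and the
  initial shear modulus $\mu_0 = 2(C_{10}+C_{01})$:
  $K_0 = 2\mu_0(1+\nu)/(3(1-2\nu))$, $D_1 = 2/K_0$. Stress is the exact
  push-forward of the closed-form second Piola–Kirchhoff stress; the
  element tangent is a per-element central difference of the first
  Piola–Kirchhoff stress (nine extra stress evaluations per element per
  iteration — cheap at the cartilage element counts involved, and immune to
  tangent-derivation errors).
* `"cartilage"`: the compressive secant law $E = 20.17\,\varepsilon +
  234\,\varepsilon^2$ for $\varepsilon<0$, zero in tension. Taken literally
  the quadratic is *negative* for $-0.0862 < \varepsilon < 0$, which would
  make the stiffness indefinite; we clamp it from below at `E_min`
  (default 0.5 MPa) and expose a `rectified` switch that reads the linear
  term as $20.17\,|\varepsilon|$ instead, since the printed sign convention
  is ambiguous. The element modulus is re-evaluated from the current
  volumetric strain at every Newton iteration (a secant update), which
  yields the strain-dependent behaviour without a bespoke consistent
  tangent.

Units of the Mooney–Rivlin coefficients are taken as MPa for consistency
with the stress unit system (mm / N / MPa throughout).

## 3. Ligaments, muscles, joints

Passive tissues are axial two-node springs with constant stiffness — the
muscle relaxant assumption of the robotic-surgery setting means only the
passive part of a Hill-type muscle acts, and the passive part is modelled
with the same spring abstraction as the ligaments. The registry
(`inst/extdata/tissue_registry.csv`, overridable per run, never edited in
code) carries the published per-spring stiffnesses and counts: nine ligament
entries totalling 37 springs and nine muscle entries of which six are active
(14 springs) — the gluteus medius/minimus and gemellus inferior are
co-modelled with their parent bundles and carry no springs of their own.
The muscle table's "k × n" notation is read as *per-spring* stiffness with a
separate count, matching how the ligament section is printed; the
attachment-area rescaling $k_s = k_{iso}\,A_s/A_{ML}$ is provided
(`scale_spring_stiffness`) but the tabulated values are used as-is by
default, since per-node areas $A_s$ are not tabulated. Springs are bilateral
(no tension-only switch is active by default; the option exists in the run
configuration) and linearised about the undeformed geometry.

Spring placement: each tissue names one origin and one insertion node patch;
the `n` springs take the `n` closest origin–insertion pairs, ordered by
distance then lowest node ids, excluding degenerate zero-length pairs. One
refinement proved necessary: for bilateral tissues whose patches span both
halves of the model, a global closest-pair rule with id tie-breaking puts
*every* spring of a mirrored tissue on one side (mirror distances tie to
machine precision and low ids win). Such tissues are therefore treated as
the symmetric pair of bundles they anatomically are: the count is split
between the left and right half-patches (left takes the odd spring) and the
closest-pair rule applies within each side.

Joints are either **tied** (the conforming interface is kept merged — the
bone-only Model I) or **mobile and frictionless**: the interface node sheet
is duplicated, the far side's elements are reassigned to the duplicates, and
each coincident pair is coupled by a penalty spring acting *only along the
interface normal* (default 10⁴ N/mm), leaving tangential sliding free.
Pair stiffnesses are weighted by each node's tributary share of the
interface area (normalised to mean one, so the joint's total normal
stiffness is unchanged); with uniform per-pair stiffness, edge and corner
nodes of the interface are over-stiff relative to their quarter/half
tributary areas and the contact force concentrates there — a discretisation
artifact, not physics. The pubic symphysis defaults to tied (its cartilage
wedge deforms; the joint itself barely moves); sacroiliac and acetabular
joints default to frictionless.

## 4. Solver

Linear 4-node tetrahedra (constant strain), plane-stress membranes and
axial springs assemble into a symmetric sparse stiffness solved by sparse
Cholesky after constraint elimination; a singular constrained system is
diagnosed by locating a connected component with no constrained degree of
freedom and naming one of its nodes. Loads are either a total force shared
equally over a node set (`load_case`, the protocol's loading) or an
area-consistent uniform traction (`consistent_surface_load`, used by the
verification suite, where exact homogeneous states are the point).

When hyperelastic or secant-cartilage elements are present, a load-stepped
Newton–Raphson path runs: 5 equal substeps, relative residual tolerance
10⁻⁶, at most 25 iterations per substep, divergence declared after two
consecutive residual increases (the residual history is attached to the
error). For displacement-controlled steps the residual is scaled by the
constraint reactions rather than the (zero) external load. All of this is
deterministic.

Stress and strain are reported per element (constant per tetrahedron;
membrane values in the element plane). Scalar summaries are the maximum and
mean von Mises stress and equivalent elastic strain
$\varepsilon_{eq} = \frac{1}{1+\nu_{\mathrm{eff}}}\sqrt{\tfrac12[(\varepsilon_1-\varepsilon_2)^2+(\varepsilon_2-\varepsilon_3)^2+(\varepsilon_3-\varepsilon_1)^2]}$,
computed over **both** the whole element set and the bone-only subset —
the averaging population behind a published "mean stress" is a genuine
modelling choice, so the report carries both conventions.

## 5. The phantom: what it emulates, and what it does not

The phantom is a stylised closed ring of structured hexahedral blocks (each
split into six tetrahedra sharing a main diagonal, which keeps face
diagonals conforming across blocks): a sacrum flanked by thin sacroiliac
cartilage layers, two innominate arcs closing anteriorly through a
pubic-symphysis cartilage wedge, femur stubs under the acetabular regions,
and a lumbar stub with a flat loading face. Default dimensions: ring width
(`overall_scale`) 180 mm, cartilage layers 4 mm, depth a quarter of the
ring width — the scale of an adult pelvis. The synthetic CT draws cortical
voxels from N(1200, 50²) HU and cancellous from N(300, 50²): values in the
range of adult pelvic CT, chosen so the two density-mapping branches are
*both* exercised (300 HU maps through the lower branch, 1200 HU through the
upper). Air is −1000 HU; the stub regions rasterise as dense bone and
cartilage as soft tissue at 100 HU.

Attachment patches are coordinate windows on the block faces, named after
the tissues they serve; the sacrospinous and sacrotuberous windows are
deliberately offset front-to-back so those springs run obliquely, as the
real ligaments do — this also supplies the anterior–posterior stiffness
that keeps the ring assembly well-posed once the joints go frictionless.
The seven measurement points sit at the phantom's homologous locations
(iliopectineal line, acetabular plate, sacrum and ilium at the sacroiliac
level, iliac fossa, ischial notch, posterior ilium), with a probe radius of
twice the mean element edge length.

What passing tests on the phantom demonstrate: that the pipeline's
machinery — mapping, constitutive laws, network construction, solving,
summarising, probing, regression — is correct and that the *protocol-level*
effect (the soft-tissue envelope lowering peak stress and mean strain)
emerges under the standing-load conditions. What they do **not**
demonstrate: agreement with any real pelvis. Absolute stresses depend on
subject geometry that is not published; accordingly the regression of
phantom probe strains against the packaged reference strain table yields a
low R² by construction, and the packaged table's role here is as a fixture
for the validation machinery (and a smoke reference), not as a target.

Known mesh-sensitivities worth naming: the phantom's re-entrant corners are
stress singularities, and spring attachment nodes are point loads, so peak
stress grows under refinement and its Model I/II comparison can flip sign
at resolutions other than the default (`block_resolution = 2`, 1248
tetrahedra, the scale at which the protocol's reduction is reported). Mean
quantities are robust. Real pelvic FE models share both artifacts; smoothed
geometry and distributed attachments would be the remedies.

## 6. Numerical and design choices

* **Units**: mm, N, MPa (N/mm²) everywhere; 17 GPa is stored as 17000 MPa.
* **Verification meshes**: the unit cube's `resolution` counts elements per
  edge; the cantilever's counts elements per *half*-depth (cross-section
  2r × 2r, 20r axial elements at 1 × 1 × 10 mm). Linear tetrahedra are
  known to be over-stiff in bending; about eight elements through the
  thickness are needed before the tip deflection lands within a few percent
  of the Euler–Bernoulli value (≈ 6 % at r = 4, converging monotonically),
  which is what the half-depth convention provides at small r.
* **Load schedule**: six magnitudes, 50–550 N in 100 N intervals (five
  intervals); the protocol descriptions that mention "five steps" and the
  printed six-column strain tables are reconciled in favour of the six
  magnitudes the tables show.
* **File formats**: VTK legacy ASCII and an Abaqus INP subset
  (NODE/ELEMENT/NSET; C3D4, S3, SPRINGA) with coordinates written at 17
  significant digits so a write/read round trip is exact to well below the
  1 nm contract; data neither dialect carries (labels, thicknesses, spring
  stiffness and action lines, VTK named sets) lives in a YAML sidecar the
  reader merges back. Volumes are NIfTI-1 with the spacing on the affine
  diagonal and the volume-corner origin in its translation.
* **Node ids** are 1-based in R; writers convert to each format's
  convention.
* **Determinism**: phantom geometry is purely deterministic; the only random
  element is CT noise, seeded from `phantom_spec(seed=)` with the caller's
  generator state restored afterwards. Newton and spring pairing are
  deterministic by construction.

## 7. Limitations

No bending stiffness in the cortical shell; no tension-only springs by
default (the pairing is linearised, so a compressed "ligament" pushes); no
frictional or large-sliding contact (the penalty pairs assume small
tangential excursions on parallel surfaces); no active muscle contraction;
no viscoelastic cartilage; element-level stress reporting only (no nodal
averaging by default). The phantom's geometry is deliberately schematic —
parametric reproducibility and analytic checks were valued over anatomical
realism, and every geometric quantity a user might want to vary is a
`phantom_spec` field.
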