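---
title: "Stiffness-matched porous superelastic NiTi fixation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stiffness-matched porous superelastic NiTi fixation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stiffmatch)
```

## The problem

Mandibular reconstruction replaces a resected segment of the lower jaw
with a fibular graft held by metal fixation plates and screws. The
standard plate material, Ti-6Al-4V, has a Young's modulus of 112 GPa
while mandibular cortical bone sits near 10–31 GPa; the mismatch routes
chewing loads through the hardware, shielding the graft and host bone
from stress and reducing the compressive engagement of the graft–host
cuts — both associated with resorption and graft failure. Superelastic
NiTi offers a dense modulus of only 37 GPa and, with engineered
porosity, can be tuned down to the modulus of the adjacent cortical bone
(12 GPa in the molar region of the reference mandible) while recovering
several percent strain elastically.

`stiffmatch` implements the full desk-scale design-and-evaluation chain
for such hardware:

1. a superelastic constitutive model for NiTi (1D and small-strain 3D);
2. exact and voxelized geometry of the three-orthogonal-cylinder pore
   unit cell with porosity inversion;
3. a voxel hexahedral FE solver (linear, superelastic, ties,
   compression-only contact);
4. homogenization of unit cells into equivalent stress–strain curves and
   local stress reports;
5. the porosity-selection design loop with safety checks;
6. a reduced, parametric mandibular-reconstruction assembly for
   comparing dense Ti against stiffness-matched NiTi plates under bite
   and pretension loads.

## Superelastic constitutive model

The model is a phase-diagram (Boyd–Lagoudas/Auricchio family)
superelastic law. The internal variable is the martensite volume
fraction $\xi \in [0,1]$ with transformation strain
$\boldsymbol\varepsilon_t = H\,\xi\,\mathbf N$, where $H$ is the maximum
uniaxial transformation strain and $\mathbf N$ the (von Mises-unit)
deviatoric flow direction. Elastic moduli mix in series (Reuss),
$1/E(\xi) = (1-\xi)/E_A + \xi/E_M$, at fixed Poisson ratio.
Transformation is driven by linear stress–temperature lines: at
operating temperature $T$ the forward (austenite→martensite)
transformation spans

$$\sigma_{fs} = C_M (T - M_s), \qquad \sigma_{ff} = C_M (T - M_f),$$

and the reverse spans $\sigma_{rs} = C_A (T - A_s)$ down to
$\sigma_{rf} = C_A (T - A_f)$, with linear hardening in $\xi$ between
start and finish. With the measured SLM NiTi parameters
($E_A = 37$ GPa, $E_M = 42$ GPa, $\nu = 0.33$,
$M_f/M_s/A_s/A_f = 243/263/270/280$ K) and the configured defaults
$C_M = C_A = 7$ MPa/K, $H = 0.04$ at body temperature (310 K), the
uniaxial loop is the familiar flag: loading at 37 GPa to 329 MPa, a
sloped plateau to 469 MPa, unloading to the reverse plateau between
280 and 210 MPa, and return to the origin. $C_M$, $C_A$ and $H$ are
not measured quantities; they are exposed as configuration with typical
Ni-rich-NiTi compression values, and `calibrate_sma()` fits them to a
user-supplied stress–strain table.

The 3D return mapping solves the scalar plateau equation by bisection
(relative tolerance $10^{-8}$, 50 iterations) on the stress *resolved
along the transformation direction* — the signed equivalent stress.
Using unsigned von Mises here admits a spurious second root in which
the transformation strain overshoots the total strain and the stress
reverses sign; the signed form is monotone and unambiguous. The
algorithmic tangent is a symmetrized forward difference (6 extra
constitutive evaluations per Gauss point), which keeps the FE Newton
loop quadratically convergent without deriving the exact tangent of the
mixed-modulus law. The 1D model is an independent scalar implementation
used as the consistency oracle: driving the 3D model under uniaxial
stress (lateral stresses iterated to zero) reproduces the 1D curve to
$10^{-8}$ relative.

Assumptions and limits: small strain; tension–compression symmetric
(single $H$; the reference data are compression-only); no plasticity
(the yield strength 1011 MPa enters only as a safety flag); no rate,
thermal-coupling or fatigue effects.

## Pore unit cell

The lattice motif is three orthogonal cylinders of equal diameter $d$
meeting at the centre of a cube of edge $a$; the cylinders are read as
*void channels* (the only reading under which 45.7% porosity lowers the
NiTi modulus from 37 toward 12 GPa; the strut reading is available
behind a convention flag). Porosity follows from inclusion–exclusion
with the Steinmetz volumes,

$$V = 3\pi r^2 a - 3\cdot\tfrac{16}{3} r^3 + 8(2-\sqrt2) r^3,
  \qquad r = d/2,$$

so $p(d{=}a{=}1) = 0.9420$, and the pairing (d = 1 mm, p = 45.7%)
inverts to a cell edge of 1.871 mm — the edge length is never stated in
the source material and is derived from that pairing. `porosity_voxel()`
is the discretization oracle (cell-centred sampling agrees with the
analytic value to 0.25 porosity points at 64 voxels/edge), and
bisection on the strictly monotone maps provides
`solve_cell_for_porosity()` / `solve_diameter_for_porosity()`.

## Voxel FE solver

Meshes are regular trilinear hexahedra (cell-centred voxels, zero
origin), assembled element-by-element; the linear solver is
Jacobi-preconditioned conjugate gradients at a relative residual of
$10^{-8}$ — fully deterministic. The patch test is exact: affine
boundary displacements reproduce a uniform strain field to round-off,
and the test suite asserts von Mises uniformity to $10^{-10}$
relative. Prescribed displacements are eliminated by projection;
reactions are recovered from the assembled product $K u$.

Interfaces couple coincident nodes that are *duplicated* between
contact groups of the mesh: tie springs (both normal and tangential
stiffness, penalty $100\,E\,h$) model screws and healed junctions;
compression-only normal springs with an outer active-set iteration
model the frictionless (friction factor 0) graft–host cuts of the
healing period, and the fully bonded variant covers the friction
factor 1 endpoint. The superelastic path is displacement-driven full
Newton with the algorithmic tangent, an inexact inner CG tolerance
slaved to the nonlinear residual, a secant predictor across increments,
and increment bisection on non-convergence.

## Homogenization: two boundary-condition families

Two estimates of the equivalent behaviour are provided, and they play
different roles.

**Uniaxial-stress single cell** (`equivalent_modulus()`,
`equivalent_curve()`): uniform normal displacement on two opposite
faces, lateral faces traction-free. Equivalent stress is the face
reaction over the projected area $a^2$; equivalent strain the face
displacement over $a$. This emulates a compression test on an isolated
specimen, which is what the 2%-strain safety checks describe.

**Periodic** (`periodic_cell_stiffness()`): the displacement splits into
an affine part plus a periodic fluctuation; the cubic symmetry of the
cell turns one solve (unit axial macro strain) into the full cubic
stiffness, and $E = (C_{11}-C_{12})(C_{11}+2C_{12})/(C_{11}+C_{12})$.
This is the right estimate for a cell in the *interior of a tiled
plate*, and it is what the design loop uses. The distinction matters:
the free faces of an isolated cell cut its surface struts, which makes
the single-cell family systematically soft — at 45.7% porosity the
NiTi cell homogenizes to 10.8 GPa (uniaxial) versus 12.2–12.3 GPa
(periodic) at 48 voxels/edge, and the discrepancy grows with porosity.
Because the fixation plate interior is a periodic tiling, porosity
selection uses the periodic family; the uniaxial family remains the
compression-sample emulation and is reported alongside.

## Local stress and the cusp filter

Porous cells concentrate stress. Two geometric features produce
*singular* stress concentrations on this lattice: re-entrant edges
where the pore cylinders intersect. A maximum taken over elements
therefore grows without bound under mesh refinement (measured on the
Ti cell at 2% strain: raw maxima 5143/5420/10703 MPa at 32/48/64
voxels/edge), and no single-element exclusion can repair an entire
singular edge. The package reports three values per curve step: the
raw maximum, the single-highest-element filtered maximum (dropped only
when it exceeds three times the runner-up), and the **cusp-filtered
peak** — the 99th volume percentile of element-centroid von Mises over
solid elements. The percentile was selected by a mesh-stability
criterion (the highest of {99, 99.5, 99.9, 100} changing by less than
3% across the two finest meshes): on the Ti cell it measures
3854/3937/3853 MPa across 32/48/64 voxels/edge, and on the
superelastic cell 457/460 MPa across 16/24. Amplification factors and
yield flags use the cusp-filtered peak; the raw values are always
carried along.

For the superelastic cell the plateau caps local stresses until the
transformation completes; at the singular cusp it does complete, and
the raw maximum then re-diverges along the martensite elastic branch —
another reason the volume-stable measure is the honest summary.

## Design loop

`solve_porosity_for_modulus()` inverts the strictly monotone
porosity–modulus map: a relative-density power-law seed
($E/E_d \approx (1-p)^2$), direct FE bracketing, then safeguarded
regula falsi. At fixed resolution the voxelized modulus is piecewise
constant in porosity, so iteration stops at the voxel granularity
($0.15/\mathrm{resolution}$ in porosity) and returns the best iterate.
Defaults: pore diameter 1 mm, periodic family, 64 voxels/edge, modulus
tolerance 0.1 GPa — each design run is four to five periodic solves of
a few seconds each. With these conditions the 12 GPa bone target yields 47.4%
porosity for NiTi and 74.7% for Ti-6Al-4V. `safety_check()` then
drives the designed cell to 2% equivalent strain (the strain cortical
bone can recover) and flags yield exceedance: the porous Ti design
fails (peak far above the 970–1030 MPa band), the porous NiTi design
passes (peak well below 1011 MPa) — within this model NiTi local
strains are recoverable whenever the stress stays below yield, since
plasticity is not modelled.

## The reduced mandibular assembly

No CT anatomy ships with the package; the comparison stage runs on a
parametric, prismatic stand-in that preserves the topology, dimensions
and load paths of the reconstruction: two host segments (cortical
shell over cancellous core, 3 mm cortex), a 40 × 14 × 38 mm
double-barrel graft block (with a cortical band at the barrel
junction), a 78 × 4 × 1.5 mm inferior plate and two 18 × 2.8 × 1 mm
superior plates one voxel off the buccal face, screws as stiff tie
springs at their catalogued positions (6 inferior, 2 per superior
plate), and compression-only contact at the two cuts. Condyle end
faces are fixed; the bite resultant (60% of 526 N) acts downward on
the molar patch of the graft top face — the coordinate convention for
the bite point is fixed here because the source leaves it open.
Pretension (100 N per plate by default; the per-plate reading of the
ambiguous wording) is realized as an axial contraction eigenstrain
$\varepsilon_0 = -F/(E A)$ in the plate mid-spans, equilibrated with
the rest of the loads; the force actually transmitted depends on the
assembly compliance, which is the physically meaningful outcome of a
pre-stretched plate screwed to bone.

Plates in the NiTi arm carry the *homogenized* equivalent response. In
all study scenarios the plate macroscopic stress stays below the
homogenized plateau onset, so the elastic branch (12 GPa) suffices and
is used; the reported "actual" plate stress multiplies the macroscopic
von Mises by the unit-cell amplification factor from the
homogenization module. Because the full-anatomy percentages of the
reference study depend on the unavailable CT geometry, regional
anisotropic bone map and muscle-vector set, the assembly is evaluated
on *ordering properties* instead: graft-region average von Mises is
strictly higher with stiffness-matched plates in scenarios A (bite),
B (pretension), and C (both); interface compressive traction increases
monotonically in pretension (0/50/100 N); the porous plate material
works harder (locally) than dense Ti at its worst case; and no tensile
traction crosses a contact interface. Host cortical bone uses the
isotropic mesiodistal modulus (17 GPa) rather than the orthotropic
table — the comparison is differential between plate arms under
identical loads, and this simplification cancels in the orderings.

## Problem sizes and numerical choices

The shipped defaults are desk-scale: design homogenizations at 64
voxels/edge (periodic, ~1 s each), modulus verifications at 48,
superelastic local-stress runs at 24 voxels/edge with 8 increments,
and the reduced assembly at 2 × 0.75 × 2 mm voxels (about 15k
elements); the test suite exercises the same code paths at these or
smaller sizes. CG tolerance is $10^{-8}$ (linear) with inexact inner
solves during Newton; return-mapping tolerance $10^{-8}$; penalty
stiffness $100\,E\,h$; all runs are deterministic, and re-running any
command with the same configuration reproduces outputs bit-identically.

## What the synthetic stage does and does not show

The generator emulates dimensions, topology, constraint scheme and
load magnitudes — not anatomy. Passing ordering tests demonstrates
that the solver chain reproduces the *mechanics* of stress shielding
and pretension engagement on a faithful reduced geometry; it does not
validate the magnitudes of the full-anatomy study (contact-pressure
and average-stress percentages, plate maxima, safety factors), which
are out of reach without the CT data. Known limitations: voxel
staircase surfaces (mitigated by the cusp filter), penalty (not
Lagrangian) contact restricted to planar matched grids, screws as
point ties without thread mechanics, single-$H$ symmetric
superelasticity, and no post-yield or fatigue modelling.
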