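# stiffmatch

Design and desk-scale evaluation of **stiffness-matched porous
superelastic NiTi fixation hardware** for mandibular reconstruction.

Standard Ti-6Al-4V fixation plates (E = 112 GPa) are an order of
magnitude stiffer than mandibular cortical bone (10–31 GPa). The
mismatch shields the bone graft from physiological stress and reduces
compressive engagement at the graft–host cuts, both linked to
resorption and reconstruction failure. Dense superelastic NiTi is far
softer (E_A = 37 GPa), and engineering porosity into it can match the
plate stiffness to the adjacent cortical bone (≈12 GPa in the molar
region) while keeping several percent of strain elastically
recoverable. `stiffmatch` implements the full design chain:

- **Superelastic constitutive model** (1D and small-strain 3D): a
  phase-diagram model with linear transformation lines
  σ_fs = C_M (T − M_s) etc., Reuss-mixed phase moduli, transformation
  strain ε_t = H ξ N, and a radial return mapping on the martensite
  fraction ξ. Calibrated from measured SLM NiTi constants
  (E_A/E_M = 37/42 GPa, ν = 0.33, M_f/M_s/A_s/A_f = 243/263/270/280 K,
  σ_y = 1011 MPa at 37 °C).
- **Tri-cylinder pore unit cell**: three orthogonal cylinder voids of
  diameter d in a cube of edge a; analytic porosity by
  inclusion–exclusion with the Steinmetz volumes
  (V = 3πr²a − 16r³ + 8(2−√2)r³), a voxel oracle, and porosity
  inversion.
- **Voxel hexahedral FE solver**: element-by-element Jacobi-PCG,
  exact patch test, tie and compression-only contact interfaces,
  eigenstrain pretension, incremental Newton for the superelastic law.
- **Homogenization**: uniaxial-stress compression-sample curves
  (equivalent stress = face reaction / projected area) and periodic
  effective stiffness (one solve via cubic symmetry); local stress
  reports with a mesh-stable cusp-filtered peak.
- **Design loop**: porosity that matches a target bone modulus, plus a
  2%-strain local-stress safety check.
- **Reduced mandibular assembly**: a parametric host/double-barrel
  graft/three-plate model with screws as ties, contact at the cuts,
  bite (60% of 526 N) and plate pretension (100 N) loads, for
  comparing dense Ti against stiffness-matched NiTi plates.

## Worked example

```r
library(stiffmatch)

p <- sma_params()          # measured SLM NiTi constants, T_op = 310 K
transformation_stresses(p)
#>  fwd_start fwd_finish  rev_start rev_finish
#>        329        469        280        210       (MPa)

# pore cell realizing 45.7% porosity with 1 mm pore channels
cell <- solve_cell_for_porosity(d = 1, target_porosity = 0.457)
cell$a
#> [1] 1.871415                                     (mm cell edge)

# homogenized modulus of that cell in NiTi (tiled-plate interior)
mesh <- voxelize_unit_cell(cell, 48)
periodic_cell_stiffness(mesh, material_linear(37, 0.33, 1011, "NiTi"))$E
#> [1] 12.32                                        (GPa; bone target: 12)

# the design loop inverted: porosity for a 12 GPa target
sel <- solve_porosity_for_modulus(design_spec(12, p))
round(100 * sel$porosity, 1)
#> [1] 47.4                                         (% porosity, NiTi)
ti <- material_linear(112, 0.3, 970, "Ti-6Al-4V")
round(100 * solve_porosity_for_modulus(design_spec(12, ti))$porosity, 1)
#> [1] 74.7                                         (% porosity, Ti-6Al-4V)
```

NiTi reaches the bone-matched stiffness at a far lower porosity than
Ti-6Al-4V — thicker struts, easier fabrication, lower local stress. The
safety check at 2% equivalent compressive strain (the strain cortical
bone can recover) makes the comparison decisive: the porous Ti design's
local peak stress (≈3900 MPa, cusp-filtered) far exceeds its yield band
(970–1030 MPa), while the superelastic NiTi design's peak (≈460 MPa)
stays well below its 1011 MPa yield because the transformation plateau
caps local stresses:

```r
safety_check(sel$cell, p)$pass
#> [1] TRUE
```

The reduced mandibular assembly then compares plate arms under the
bite and pretension scenarios:

```r
asm <- generate_assembly(assembly_config(h = c(2, 0.75, 2)))
cmp <- compare_models(asm, c("A", "B", "C"), niti_amplification = 2.4)
cmp$table[, c("scenario", "graft_ratio", "traction_NiTi", "traction_Ti")]
```

Graft-region average von Mises stress is strictly higher with the
stiffness-matched plates in every scenario (less stress shielding), and
interface compression grows monotonically with pretension.

## Layout

```
R/                  constitutive model, geometry, FE solver, homogenization,
                    design loop, reduced assembly, IO (VTK/STL/CSV/JSON), CLI
src/                C++ kernels (return mapping, element matvec, PCG)
inst/extdata/       material parameter fixtures (JSON)
inst/cli/           shell entry point (material-demo / design / porosity / compare)
tests/testthat/     unit, property and acceptance suites
scripts/            acceptance.R
vignettes/          methods vignette (models, assumptions, numerical choices)
```
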