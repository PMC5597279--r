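# Shared fixtures and a cache for quantities reused across test files.
# Everything is generated in code at test time; nothing is read from disk.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

niti_default <- function() sma_params()

ti_material <- function() material_linear(112, 0.3, 970, "Ti-6Al-4V")

niti_austenite <- function() material_linear(37, 0.33, 1011, "NiTi (austenite)")

# The bone-matched cell: pore diameter 1 mm at 45.7% porosity.
matched_cell <- function() cached("matched_cell",
                                  solve_cell_for_porosity(1, 0.457))

# Coarse reconstructed assembly reused by the comparison tests.
coarse_assembly <- function() cached("coarse_assembly", {
  generate_assembly(assembly_config(h = c(2, 0.75, 2)))
})

# Moderate-cost homogenized modulus of the matched cell.
matched_modulus_res24 <- function() cached("matched_modulus_res24", {
  mesh <- voxelize_unit_cell(matched_cell(), 24)
  equivalent_modulus(mesh, niti_austenite())
})
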