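# Stiffness-matching design loop and safety checks.

test_that("design spec validates the target range", {
  expect_error(design_spec(40, sma_params()), "target modulus")
  expect_error(design_spec(0, sma_params()), "target modulus")
  expect_silent(design_spec(12, sma_params()))
})

test_that("porosity selection round-trips to the target modulus", {
  spec <- design_spec(12, sma_params())
  sel <- solve_porosity_for_modulus(spec, resolution = 24, tol = 0.1)
  # re-homogenize the returned cell: within 2% of the target
  mesh <- voxelize_unit_cell(sel$cell, 24)
  E <- equivalent_modulus(mesh, niti_austenite())
  expect_equal(E, 12, tolerance = 0.02 * 12)
  expect_equal(porosity_analytic(sel$cell), sel$porosity, tolerance = 1e-6)
})

test_that("NiTi reaches the bone target at lower porosity than Ti-6Al-4V", {
  spec_ni <- design_spec(12, sma_params())
  spec_ti <- design_spec(12, ti_material())
  p_ni <- solve_porosity_for_modulus(spec_ni, resolution = 24, tol = 0.15)
  p_ti <- solve_porosity_for_modulus(spec_ti, resolution = 24, tol = 0.15)
  expect_lt(p_ni$porosity, p_ti$porosity)
  # same ordering for a stiffer target inside [12, 37] GPa
  p_ni2 <- solve_porosity_for_modulus(design_spec(20, sma_params()),
                                      resolution = 24, tol = 0.15)
  p_ti2 <- solve_porosity_for_modulus(design_spec(20, ti_material()),
                                      resolution = 24, tol = 0.15)
  expect_lt(p_ni2$porosity, p_ti2$porosity)
  # lower target -> higher porosity within one material
  expect_lt(p_ni2$porosity, p_ni$porosity)
})

test_that("safety check agrees with the 1D point model for a dense cell", {
  p <- sma_params()
  celld <- unit_cell(0, 1)
  saf <- safety_check(celld, p, safety_strain = 0.01, resolution = 4,
                      increments = 5)
  # oracle: the uniaxial 1D response at 1% strain
  s1d <- abs(tail(sma_loop_1d(p, seq(0.002, 0.01, length.out = 5))$stress, 1))
  expect_equal(saf$max_stress, s1d, tolerance = 0.02 * s1d)
  expect_equal(saf$safety_factor, 1011 / s1d, tolerance = 0.05)
  expect_true(saf$pass)
})

test_that("porous Ti fails and porous NiTi passes the 2% strain check", {
  # moderate resolution: the magnitudes tighten in the acceptance suite
  cell_ti <- solve_cell_for_porosity(1, 0.783)
  saf_ti <- safety_check(cell_ti, ti_material(), resolution = 24)
  expect_false(saf_ti$pass)
  expect_gt(saf_ti$max_stress, 1030)

  saf_ni <- safety_check(matched_cell(), sma_params(), resolution = 12,
                         increments = 5)
  expect_true(saf_ni$pass)
  expect_lt(saf_ni$max_stress, 1011)
})

test_that("design report assembles a serializable summary", {
  spec <- design_spec(12, sma_params())
  rep <- design_report(spec, resolution = 16, safety_resolution = 12,
                       tol = 0.2)
  expect_true(rep$pass)
  expect_equal(rep$pore_diameter_mm, 1)
  expect_gt(rep$porosity, 0.2)
  expect_lt(rep$porosity, 0.7)
  tf <- tempfile(fileext = ".json")
  write_report_json(rep, tf)
  back <- read_config(tf)
  expect_equal(back$porosity, rep$porosity, tolerance = 1e-8)
})
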