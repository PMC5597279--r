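# Homogenization: equivalent curves, modulus bounds, local amplification,
# and the porosity-modulus sweep.

test_that("a fully dense linear cell recovers its material modulus", {
  mesh <- voxelize_unit_cell(unit_cell(0, 1), 8)
  E <- equivalent_modulus(mesh, ti_material(), cg_tol = 1e-12)
  expect_equal(E, 112, tolerance = 0.01 * 112)
})

test_that("equivalent curves: dense amplification is 1, porous exceeds 1", {
  dense <- voxelize_unit_cell(unit_cell(0, 1), 6)
  rd <- equivalent_curve(dense, ti_material(), max_strain = 0.02,
                         cg_tol = 1e-11)
  rep_d <- local_stress_report(rd, 0.02, sigma_y = 970)
  expect_equal(rep_d$amplification, 1, tolerance = 1e-6)
  # dense Ti at 2%: sigma = E * eps = 2240 MPa, above the yield band
  expect_equal(rep_d$max_vm, 112e3 * 0.02, tolerance = 0.01 * 2240)
  expect_true(rep_d$exceeds_yield)

  porous <- voxelize_unit_cell(matched_cell(), 16)
  rp <- equivalent_curve(porous, niti_austenite(), max_strain = 0.02)
  rep_p <- local_stress_report(rp, 0.02, sigma_y = 1011)
  expect_gt(rep_p$amplification, 1)
  # max local von Mises bounds the equivalent stress at every step
  expect_true(all(rp$vm_max >= rp$stress - 1e-9))
  # out-of-range request errors
  expect_error(local_stress_report(rp, 0.05, 1011), "outside")
})

test_that("porosity-modulus sweep is strictly monotone and Voigt-bounded", {
  ps <- c(0, 0.25, 0.457, 0.65, 0.8)
  sw <- porosity_modulus_sweep(niti_default(), ps, resolution = 24)
  expect_equal(sw$modulus[1], 37)
  expect_true(all(diff(sw$modulus) < 0))
  # Voigt (rule-of-mixtures) upper bound
  expect_true(all(sw$modulus <= (1 - sw$porosity) * 37 + 1e-9))
  # vanishing-solid limit: the most porous cell is far softer than dense
  expect_lt(sw$modulus[length(ps)] / 37, 0.25)
})

test_that("superelastic porous cell: plateau onset below the dense plateau", {
  mesh <- voxelize_unit_cell(matched_cell(), 12)
  p <- sma_params()
  resp <- equivalent_curve(mesh, p, max_strain = 0.02, increments = 5)
  # the porous equivalent stress at 2% sits far below the dense response
  d1 <- sma_loop_1d(p, seq(0.004, 0.02, length.out = 5))
  expect_lt(max(resp$stress), max(abs(d1$stress)))
  # transformation has started locally even though the equivalent stress
  # is below the dense forward-start stress
  expect_gt(max(resp$xi), 0)
  expect_lt(max(resp$stress), 329)
})

test_that("equivalent modulus agrees between linear and superelastic paths", {
  mesh <- voxelize_unit_cell(matched_cell(), 12)
  p <- sma_params()
  Elin <- equivalent_modulus(mesh, material_linear(p$E_A, p$nu))
  resp <- equivalent_curve(mesh, p, max_strain = 0.004, increments = 4)
  expect_equal(resp$modulus, Elin, tolerance = 0.02 * Elin)
})
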