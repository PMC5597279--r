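# Superelastic constitutive model: transformation stresses, loop shape,
# state invariants, and 1D/3D consistency.

test_that("transformation stresses follow the Clausius-Clapeyron lines", {
  p <- sma_params()
  s <- transformation_stresses(p)
  # direct products of the configured slopes with the Table-temperature gaps
  expect_equal(s[["fwd_start"]], 7 * (310 - 263))   # 329 MPa
  expect_equal(s[["fwd_finish"]], 7 * (310 - 243))
  expect_equal(s[["rev_start"]], 7 * (310 - 270))
  expect_equal(s[["rev_finish"]], 7 * (310 - 280))  # 210 MPa
  expect_lt(s[["fwd_start"]], s[["fwd_finish"]])
  expect_lt(s[["rev_finish"]], s[["rev_start"]])
  # the forward start stress vanishes as T_op approaches Ms (zero-gap
  # limit of the construction, probed on the formula through Ms -> T_op)
  p2 <- sma_params(T_op = 285)
  expect_equal(transformation_stresses(p2)[["fwd_start"]], 7 * (285 - 263))
})

test_that("parameter validation rejects unphysical sets", {
  expect_error(sma_params(Ms = 275, As = 270), "Mf < Ms < As < Af")
  expect_error(sma_params(nu = 0.6), "nu")
  expect_error(sma_params(E_A = -1))
  expect_error(transformation_stresses(sma_params(T_op = 275)), "T_op")
})

test_that("1D model: elastic slope, plateau, loop closure, dissipation", {
  p <- sma_params()
  # austenite elastic slope: 37 GPa exactly
  r <- integrate_point_1d(p, strain_increment = 1e-4)
  expect_equal(r$stress, 3.7, tolerance = 1e-12)
  expect_equal(r$state$xi, 0)
  # zero strain from virgin state
  r0 <- integrate_point_1d(p, strain_increment = 0)
  expect_equal(r0$stress, 0)
  # load to ~800 MPa (through full transformation into elastic
  # martensite), unload to zero strain: closed loop, positive dissipation
  e800 <- 0.04 + 800 / 42e3  # transformation strain + martensite elastic
  path <- seq(0, e800, length.out = 150)
  loop <- sma_loop_1d(p, c(path, rev(path)[-1]))
  expect_gt(max(loop$stress), 790)
  expect_lt(abs(loop$stress[nrow(loop)]), 1)        # closes to < 1 MPa
  expect_lt(attr(loop, "state")$xi, 1e-3)
  expect_lt(abs(attr(loop, "state")$eps_t), 1e-4)   # residual strain
  expect_gt(loop_dissipation(loop$strain, loop$stress), 0)
  # forward plateau: xi monotone non-decreasing during loading
  expect_true(all(diff(loop$xi[seq_along(path)]) > -1e-12))
  # strain cap enforcement
  expect_error(integrate_point_1d(p, strain_increment = 0.08), "cap")
})

test_that("state invariants hold along random strain histories", {
  p <- sma_params()
  set.seed(42)
  xi_lo <- xi_hi <- et_excess <- -Inf
  for (rep in 1:5) {
    targets <- cumsum(stats::rnorm(40, sd = 0.008))
    targets <- pmax(pmin(targets, 0.055), -0.055)
    st <- sma_state()
    for (tg in targets) {
      r <- integrate_point_1d(p, st, tg - st$eps)
      st <- r$state
      xi_lo <- max(xi_lo, -st$xi)
      xi_hi <- max(xi_hi, st$xi - 1)
      # transformation strain magnitude bounded by H * xi
      et_excess <- max(et_excess, abs(st$eps_t) - p$H * st$xi)
    }
  }
  expect_lte(xi_lo, 0)
  expect_lte(xi_hi, 0)
  expect_lte(et_excess, 1e-10)
})

test_that("3D model reduces to 1D under uniaxial stress within 0.5%", {
  p <- sma_params()
  up <- seq(0.002, 0.05, length.out = 20)
  path <- c(up, rev(up)[-1])
  d3 <- drive_uniaxial_3d(p, path)
  d1 <- sma_loop_1d(p, path)
  expect_lt(max(abs(d3$stress - d1$stress) / pmax(abs(d1$stress), 1)), 0.005)
  # off-axis stresses vanish under the mixed control
  expect_lt(max(d3$lateral_stress) / max(abs(d3$stress)), 1e-6)
})

test_that("3D model: hydrostatic elasticity, isotropy, SPD tangent", {
  p <- sma_params()
  # hydrostatic strain stays elastic: bulk response from (E_A, nu)
  e <- 1e-3
  r <- integrate_point_3d(p, strain_increment = c(e, e, e, 0, 0, 0))
  K <- 37e3 / (3 * (1 - 2 * 0.33))
  expect_equal(r$stress[1:3], rep(3 * K * e, 3), tolerance = 1e-6)
  expect_equal(r$state$xi, 0)
  ev <- eigen(r$tangent, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # frame indifference: loading axis permutation permutes the stress
  ra <- integrate_point_3d(p, strain_increment = c(0.01, 0, 0, 0, 0, 0))
  rb <- integrate_point_3d(p, strain_increment = c(0, 0, 0.01, 0, 0, 0))
  expect_equal(ra$stress[c(1, 2, 3)], rb$stress[c(3, 2, 1)], tolerance = 1e-9)
  expect_equal(ra$state$xi, rb$state$xi, tolerance = 1e-9)
})

test_that("calibration recovers plateau constants from a synthetic curve", {
  truth <- sma_params(C_M = 8.5, H = 0.035)
  sim <- sma_curve_1d(truth, 0.045, n = 45)
  fit <- calibrate_sma(sma_params(), sim$strain, sim$stress)
  expect_equal(fit$C_M, 8.5, tolerance = 0.05)
  expect_equal(fit$H, 0.035, tolerance = 0.05)
})
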