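# Voxel FE solver: patch test, equilibrium, ties, contact, and the
# incremental superelastic path.

test_that("patch test: affine boundary displacements reproduce uniform strain", {
  mesh <- voxelize_unit_cell(unit_cell(0, 1), 6)
  ti <- ti_material()
  # affine field u = A x on every boundary node
  A <- matrix(c(0.01, 0.002, 0, 0.002, -0.003, 0.001, 0, 0.001, 0.005), 3, 3)
  A <- (A + t(A)) / 2
  xyz <- mesh$node_xyz
  onb <- which(apply(xyz, 1, function(x) any(abs(x) < 1e-9 | abs(x - 1) < 1e-9)))
  uaff <- xyz %*% A
  # prescribe the exact affine value per node and component
  fixsets <- list()
  for (c in 1:3) {
    for (i in seq_along(onb)) {
      fixsets[[length(fixsets) + 1]] <- bc_fix(onb[i], c, uaff[onb[i], c])
    }
  }
  res <- fe_solve_linear(mesh, list(ti), fixsets, cg_tol = 1e-13)
  # element strains equal the prescribed uniform strain to near round-off
  eps_exp <- c(diag(A), 2 * A[1, 2], 2 * A[2, 3], 2 * A[1, 3])
  err <- max(abs(res$strain - eps_exp))
  expect_lt(err / max(abs(eps_exp)), 1e-10)
  # von Mises uniform to 1e-10 relative
  expect_lt((max(res$vm) - min(res$vm)) / max(res$vm), 1e-10)
})

test_that("single voxel under uniaxial-stress conditions gives sigma = E eps", {
  mesh <- voxel_mesh(array(1L, c(1, 1, 1)), h = 1)
  ti <- ti_material()
  E <- equivalent_modulus(mesh, ti, strain = 0.01, cg_tol = 1e-13)
  expect_equal(E, 112, tolerance = 1e-8)
  bc <- cell_uniaxial_bc(mesh, 0.01)
  res <- fe_solve_linear(mesh, list(ti), bc$fix, cg_tol = 1e-13)
  expect_equal(res$sigma[3, 1], -112e3 * 0.01, tolerance = 1e-6)
  expect_lt(abs(res$sigma[1, 1]), 1e-6 * abs(res$sigma[3, 1]))
})

test_that("reactions balance applied forces and the mesh must be constrained", {
  cell <- solve_cell_for_porosity(1, 0.5)
  mesh <- voxelize_unit_cell(cell, 12)
  ti <- ti_material()
  bot <- nodes_on_plane(mesh, 3, 0)
  top <- nodes_on_plane(mesh, 3, cell$a)
  fix <- list(bc_fix(bot, 1:3, 0))
  force <- list(bc_force(top, 3, -50))
  res <- fe_solve_linear(mesh, list(ti), fix, force, cg_tol = 1e-10)
  Rz <- sum(res$reactions[3 * (bot - 1) + 3])
  expect_equal(Rz, 50, tolerance = 1e-6 * 50)   # equilibrium
  expect_error(fe_solve_linear(mesh, list(ti), list(), force), "constraint")
})

test_that("two tied blocks behave as a single block", {
  # 4x4x8 bar split into two contact groups at z = 4, tied by stiff springs
  tag <- array(1L, c(4, 4, 8))
  grp <- array(1L, c(4, 4, 8))
  grp[, , 5:8] <- 2L
  split <- voxel_mesh(tag, h = 1, grp = grp)
  mono <- voxel_mesh(tag, h = 1)
  ti <- ti_material()
  pairs <- contact_node_pairs(split, 1L, 2L)
  expect_equal(nrow(pairs), 25)
  kn <- 100 * 112e3 * 1
  springs <- make_springs(pairs, kn, kn, c(0, 0, 1))
  solve_bar <- function(mesh, springs = NULL) {
    bot <- nodes_on_plane(mesh, 3, 0)
    top <- nodes_on_plane(mesh, 3, 8)
    fix <- list(bc_fix(bot, 1:3, 0))
    force <- list(bc_force(top, 3, -1000))
    fe_solve_linear(mesh, list(ti), fix, force, springs = springs,
                    cg_tol = 1e-11)
  }
  rs <- solve_bar(split, springs)
  rm <- solve_bar(mono)
  expect_equal(max(abs(rs$u)), max(abs(rm$u)), tolerance = 0.02)
  expect_equal(mean(rs$vm), mean(rm$vm), tolerance = 0.02)
})

test_that("contact interfaces transmit compression but never tension", {
  tag <- array(1L, c(3, 3, 6))
  grp <- array(1L, c(3, 3, 6))
  grp[, , 4:6] <- 2L
  mesh <- voxel_mesh(tag, h = 1, grp = grp)
  ti <- ti_material()
  pairs <- contact_node_pairs(mesh, 1L, 2L)
  kn <- 100 * 112e3
  springs <- make_springs(pairs, kn, 0, c(0, 0, 1))
  bot <- nodes_on_plane(mesh, 3, 0)
  top <- nodes_on_plane(mesh, 3, 6)
  fix <- list(bc_fix(bot, 1:3, 0), bc_fix(top, 1:2, 0))
  crows <- seq_len(nrow(springs))
  # compression: force transmitted, all normal forces compressive
  resc <- fe_solve_contact(mesh, list(ti), fix,
                           list(bc_force(top, 3, -900)), springs, crows,
                           cg_tol = 1e-10)
  Rz <- sum(resc$reactions[3 * (bot - 1) + 3])
  expect_equal(Rz, 900, tolerance = 1e-4 * 900)
  expect_true(all(resc$spring_normal_force > -1e-8))
  # tension (displacement-controlled so the separated block stays
  # constrained): the gap opens and nothing is transmitted
  fix_t <- list(bc_fix(bot, 1:3, 0), bc_fix(top, 1:2, 0),
                bc_fix(top, 3, 0.1))
  rest <- fe_solve_contact(mesh, list(ti), fix_t, springs = springs,
                           contact_rows = crows, cg_tol = 1e-10)
  Rz_t <- sum(rest$reactions[3 * (bot - 1) + 3])
  expect_lt(abs(Rz_t), 1e-6 * abs(900))
  expect_true(all(abs(rest$spring_normal_force) < 1e-8))
  # the upper block moves away rigidly: the gap change equals the pull
  gap <- rest$u[3 * (pairs[, 2] - 1) + 3] - rest$u[3 * (pairs[, 1] - 1) + 3]
  expect_true(all(gap > 0.099))
})

test_that("superelastic FE: elastic branch matches the linear solve", {
  mesh <- voxelize_unit_cell(unit_cell(0, 1), 4)
  p <- sma_params()
  # below the forward start stress the response is austenite-elastic
  bc <- cell_uniaxial_bc(mesh, 0.005)   # 185 MPa < 329 MPa
  lin <- fe_solve_linear(mesh, list(material_linear(p$E_A, p$nu)), bc$fix,
                         cg_tol = 1e-11)
  sol <- fe_solve_sma(mesh, p, bc$fix, n_increments = 2,
                      track = bc_fix(bc$top, 3, 0))
  expect_equal(max(abs(sol$u - lin$u)), 0, tolerance = 1e-7)
  expect_equal(max(sol$xi), 0)
})

test_that("superelastic FE: a dense cube crosses the plateau and unloads closed", {
  mesh <- voxelize_unit_cell(unit_cell(0, 1), 3)
  p <- sma_params()
  bc <- cell_uniaxial_bc(mesh, 0.03)
  trk <- bc_fix(bc$top, 3, 0)
  sol <- fe_solve_sma(mesh, p, bc$fix, n_increments = 6, track = trk)
  s_eq <- abs(sol$steps$reaction) / 1   # area 1 mm^2
  # macroscopic stress sits on the transformation plateau, and matches the
  # 1D point model driven to the same strain
  d1 <- sma_loop_1d(p, sol$steps$lambda * 0.03)
  expect_equal(s_eq, abs(d1$stress), tolerance = 0.01)
  expect_gt(max(sol$xi), 0.2)
  # unload by reversing the prescribed displacement: loop closes
  # (drive a fresh run up then down via two chained solves on the state)
  # loop closure at the point level is covered in test-sma-material; here
  # we check path consistency: halving the increments changes the final
  # reaction by < 1%
  sol2 <- fe_solve_sma(mesh, p, bc$fix, n_increments = 12, track = trk)
  expect_equal(tail(abs(sol2$steps$reaction), 1), tail(s_eq, 1),
               tolerance = 0.01)
})

test_that("eigenstrain pretension produces the intended axial force", {
  # clamped-clamped bar with a contraction eigenstrain in the middle
  tag <- array(1L, c(12, 2, 2))
  mesh <- voxel_mesh(tag, h = 0.5)
  ti <- ti_material()
  ends <- c(nodes_on_plane(mesh, 1, 0), nodes_on_plane(mesh, 1, 6))
  fix <- list(bc_fix(ends, 1:3, 0))
  eps0 <- matrix(0, 6, nrow(mesh$elem_ijk))
  cen <- element_centroids(mesh)
  mid <- which(cen[, 1] > 1.5 & cen[, 1] < 4.5)
  A <- 1 * 1  # cross-section mm^2
  F_target <- 100
  eps0[1, mid] <- -F_target / (112e3 * A)
  res <- fe_solve_linear(mesh, list(ti), fix, eigenstrain = eps0,
                         cg_tol = 1e-11)
  # clamped-clamped 1D solution: the realized force is the eigenstrain
  # force scaled by the pre-stretched fraction of the bar length (here 1/2)
  Rx <- sum(res$reactions[3 * (nodes_on_plane(mesh, 1, 0) - 1) + 1])
  expect_equal(abs(Rx), F_target / 2, tolerance = 0.03 * F_target)
  # the mid-section is in tension along x
  expect_gt(mean(res$sigma[1, mid]), 0)
})
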