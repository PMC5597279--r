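# Tri-cylinder cell geometry: analytic porosity, the voxel oracle,
# porosity inversion, and plate solids.

test_that("analytic porosity matches the inclusion-exclusion values", {
  expect_equal(porosity_analytic(unit_cell(0, 1)), 0)
  # d = a = 1: 3 pi r^2 a - 3 (16/3) r^3 + 8 (2 - sqrt 2) r^3 at r = 0.5
  expect_equal(porosity_analytic(unit_cell(1, 1)), 0.9420, tolerance = 1e-4)
  # the 1 mm pore / 45.7% porosity pairing implies a ~ 1.87 mm
  cell <- solve_cell_for_porosity(1, 0.457)
  expect_equal(cell$a, 1.87, tolerance = 0.01)
  expect_equal(porosity_analytic(cell), 0.457, tolerance = 1e-6)
  # strut convention is the complement
  expect_equal(porosity_analytic(unit_cell(1, 1.5, "strut")),
               1 - porosity_analytic(unit_cell(1, 1.5, "void")))
  expect_error(unit_cell(1.2, 1), "protrude")
})

test_that("porosity is strictly monotone in d and in a", {
  ds <- seq(0.1, 1.4, length.out = 12)
  pd <- vapply(ds, function(d) porosity_analytic(unit_cell(d, 1.5)), 0)
  expect_true(all(diff(pd) > 0))
  as <- seq(1.1, 3, length.out = 12)
  pa <- vapply(as, function(a) porosity_analytic(unit_cell(1, a)), 0)
  expect_true(all(diff(pa) < 0))
})

test_that("voxel porosity converges to the analytic value", {
  cell <- solve_cell_for_porosity(1, 0.457)
  err <- vapply(c(8, 16, 32, 64), function(r) {
    abs(porosity_voxel(cell, r) - 0.457)
  }, 0)
  expect_lt(err[4], 0.005)           # resolution 64: within half a point
  expect_lt(err[4], err[1])          # refinement reduces the error
  # degenerate cases
  expect_equal(porosity_voxel(unit_cell(0, 1), 16), 0)
  expect_equal(porosity_voxel(unit_cell(1, 1), 64), 0.942, tolerance = 0.005)
  expect_error(porosity_voxel(cell, 4))
})

test_that("porosity inversion round-trips and flags unattainable targets", {
  for (tgt in c(0.2, 0.457, 0.7)) {
    cell <- solve_cell_for_porosity(1, tgt)
    expect_equal(porosity_analytic(cell), tgt, tolerance = 1e-6)
  }
  dual <- solve_diameter_for_porosity(1.87, 0.457)
  expect_equal(dual$d, 1, tolerance = 0.01)
  expect_equal(solve_diameter_for_porosity(2, 0)$d, 0)
  expect_error(solve_cell_for_porosity(1, 0.96), "unattainable")
  expect_error(solve_diameter_for_porosity(1, 0.96), "unattainable")
})

test_that("voxelized cell has the right solid fraction and symmetry", {
  cell <- solve_cell_for_porosity(1, 0.457)
  mesh <- voxelize_unit_cell(cell, 48)
  expect_equal(mesh_solid_fraction(mesh), 1 - 0.457, tolerance = 0.01)
  # mirror symmetry of the indicator across all three mid-planes
  ind <- array(0L, mesh$dim)
  ind[mesh$elem_lin] <- 1L
  expect_identical(ind, ind[rev(seq_len(dim(ind)[1])), , ])
  expect_identical(ind, ind[, rev(seq_len(dim(ind)[2])), ])
  expect_identical(ind, ind[, , rev(seq_len(dim(ind)[3]))])
  # dense cell: every voxel solid
  dense <- voxelize_unit_cell(unit_cell(0, 1), 8)
  expect_equal(mesh_solid_fraction(dense), 1)
  expect_error(voxelize_unit_cell(cell, 8), "under-resolved")
})

test_that("plate solids carry a dense shell, pores, and screw holes", {
  cell <- solve_cell_for_porosity(1, 0.457)
  pl <- plate_solid(18, 2.8, 1, cell, shell = 0.2,
                    screw_x = c(4, 14), screw_diameter = 1.4)
  mesh <- build_plate(pl, h = 0.1)
  ind <- array(0L, mesh$dim)
  ind[mesh$elem_lin] <- 1L
  # boundary voxel layers lie inside the 0.2 mm shell: fully dense except
  # where screw holes pierce them
  rs2 <- 0.7^2
  xs <- (seq_len(dim(ind)[1]) - 0.5) * 0.1
  zs <- (seq_len(dim(ind)[3]) - 0.5) * 0.1
  in_hole <- outer(xs, zs, function(x, z) {
    (x - 4)^2 + (z - 2.8 / 2)^2 < rs2 | (x - 14)^2 + (z - 2.8 / 2)^2 < rs2
  })
  expect_true(all(ind[, 1, ][!in_hole] == 1L))
  expect_true(all(ind[, dim(ind)[2], ][!in_hole] == 1L))
  # screw holes are void through the whole thickness at the hole axes
  expect_true(all(ind[40, , 14] == 0L))   # centre column of the x = 4 hole
  expect_true(all(ind[140, , 14] == 0L))  # centre column of the x = 14 hole
  # interior porosity near the unit-cell value (the 1 mm plate is thinner
  # than one 1.87 mm cell, so partial-cell truncation shifts it), and the
  # dense shell pulls the whole-plate value below the interior one
  expect_gt(attr(mesh, "porosity_interior"), 0.38)
  expect_lt(attr(mesh, "porosity_interior"), 0.58)
  expect_lt(attr(mesh, "porosity_whole"), attr(mesh, "porosity_interior"))
  # dense plate: full box
  dm <- build_plate(plate_solid(10, 2, 1), h = 0.25)
  expect_equal(mesh_solid_fraction(dm), 1)
})
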