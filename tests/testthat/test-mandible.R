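# Reduced mandibular-reconstruction assembly: geometry, load scenarios,
# and the Ti-vs-NiTi ordering properties at coarse resolution.

test_that("assembly geometry matches the configured dimensions", {
  asm <- coarse_assembly()
  mesh <- asm$mesh
  vol_el <- prod(mesh$h)
  # graft block: 40 x 14 x 38 mm within one voxel layer
  graft_vol <- sum(asm$region %in% c("graft_cortical", "graft_cancellous")) *
    vol_el
  expect_equal(graft_vol, 40 * 14 * 38, tolerance = 0.05)
  # plates exist and sit off the buccal face
  expect_gt(sum(asm$region == "plate"), 0)
  plate_y <- element_centroids(mesh)[asm$region == "plate", 2]
  expect_true(all(plate_y > asm$config$graft_width))
  # two contact interfaces with matched node pairs
  expect_gt(nrow(asm$interfaces$mesial$pairs), 10)
  expect_gt(nrow(asm$interfaces$distal$pairs), 10)
  # load path is connected once springs are accounted for: bone continuity
  # within each group plus plates as separate components
  expect_gte(mesh_n_components(mesh), 4)
})

test_that("healthy (unresected) variant is a single contiguous bone", {
  asm <- generate_assembly(assembly_config(h = c(2, 1, 2)), resected = FALSE)
  expect_equal(mesh_n_components(asm$mesh), 1)
  expect_true(all(asm$region %in% c("host_cortical", "host_cancellous")))
})

test_that("rest scenario without pretension leaves the assembly unloaded", {
  asm <- coarse_assembly()
  out <- apply_scenario(asm, load_scenario("rest"), plate = "Ti")
  expect_lt(max(out$result$vm), 1e-6)
  expect_equal(out$interface_traction$mean_compressive, 0, tolerance = 1e-9)
})

test_that("interface compression increases monotonically with pretension", {
  asm <- coarse_assembly()
  sw <- cached("pretension_sweep",
               pretension_sweep(asm, c(0, 50, 100), plate = "NiTi"))
  expect_true(all(diff(sw$mean_compressive) > 0))
  # pretension alone produces compression, not tension, at the cuts
  expect_gte(sw$mean_compressive[1], 0)
})

test_that("no tensile traction crosses a contact-mode interface", {
  asm <- coarse_assembly()
  cmp <- cached("coarse_compare", {
    compare_models(asm, c("A", "B", "C"), niti_amplification = 2.4)
  })
  for (sc in c("A", "B", "C")) {
    for (arm in c("Ti", "NiTi")) {
      expect_lt(cmp$runs[[sc]][[arm]]$interface_traction$max_tensile_force,
                1e-6)
    }
  }
})

test_that("stiffness-matched plates raise graft stress in all scenarios", {
  asm <- coarse_assembly()
  cmp <- cached("coarse_compare", {
    compare_models(asm, c("A", "B", "C"), niti_amplification = 2.4)
  })
  tab <- cmp$table
  # stress shielding direction: graft sees more load with compliant plates
  expect_true(all(tab$graft_ratio > 1))
  # interface engagement is never reduced by the compliant plates
  expect_true(all(tab$traction_NiTi >= tab$traction_Ti - 1e-9))
  # the porous plate material works harder than dense Ti at its worst case
  expect_gt(max(tab$plate_local_NiTi), max(tab$plate_local_Ti))
  expect_true(all(is.finite(as.matrix(tab[, -1]))))
})

test_that("plate-stiffness ladder: graft stress never decreases with softer plates", {
  asm <- coarse_assembly()
  cmp <- cached("coarse_compare", {
    compare_models(asm, c("A", "B", "C"), niti_amplification = 2.4)
  })
  graft_of <- function(out) {
    out$summary$mean_vm[out$summary$region == "graft_cortical"]
  }
  # three-point ladder under scenario A: 112 (dense Ti), 37 (dense NiTi),
  # 12 GPa (bone-matched porous); the end points reuse the comparison runs
  mid <- apply_scenario(asm, load_scenario("A"), plate = "NiTi",
                        plate_modulus = 37)
  g <- c(graft_of(cmp$runs$A$Ti), graft_of(mid), graft_of(cmp$runs$A$NiTi))
  expect_true(all(diff(g) > -1e-9))
})

test_that("re-running a scenario reproduces the fields bit-identically", {
  asm <- coarse_assembly()
  cmp <- cached("coarse_compare", {
    compare_models(asm, c("A", "B", "C"), niti_amplification = 2.4)
  })
  again <- apply_scenario(asm, load_scenario("A"), plate = "Ti")
  expect_identical(again$result$u, cmp$runs$A$Ti$result$u)
  expect_identical(again$summary$mean_vm, cmp$runs$A$Ti$summary$mean_vm)
})
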