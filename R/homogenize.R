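#' Uniaxial-stress boundary conditions for a cell mesh
#'
#' Compression along an axis: uniform normal displacement on the two
#' opposing faces, lateral faces traction-free.  In-plane rigid modes are
#' removed by pinning one bottom-face node in both lateral directions and
#' a second in one direction.
#'
#' @param mesh A cell [voxel_mesh()] (zero origin).
#' @param strain Equivalent compressive strain (positive number; the top
#'   face moves by `-strain * L`).
#' @param axis Loading axis (default 3).
#' @return List with the `fix` sets, the top node set and the specimen
#'   length and cross-section area.
#' @export
cell_uniaxial_bc <- function(mesh, strain, axis = 3) {
  L <- mesh$dim[axis] * mesh$h[axis]
  lat <- setdiff(1:3, axis)
  bot <- nodes_on_plane(mesh, axis, 0)
  top <- nodes_on_plane(mesh, axis, L)
  if (length(bot) == 0 || length(top) == 0) stop("cell faces carry no nodes")
  ctr <- c(mesh$dim * mesh$h / 2)
  xyz <- mesh$node_xyz[bot, , drop = FALSE]
  d2 <- (xyz[, lat[1]] - ctr[lat[1]])^2 + (xyz[, lat[2]] - ctr[lat[2]])^2
  pin1 <- bot[which.min(d2)]
  # second pin: offset along lat[1] from pin1, restrain lat[2] (kills the
  # in-plane rotation)
  off <- abs(xyz[, lat[1]] - mesh$node_xyz[pin1, lat[1]])
  pin2 <- bot[which.max(off)]
  fix <- list(bc_fix(bot, axis, 0),
              bc_fix(top, axis, -strain * L),
              bc_fix(pin1, lat, 0),
              bc_fix(pin2, lat[2], 0))
  area <- prod((mesh$dim * mesh$h)[lat])
  list(fix = fix, top = top, bottom = bot, axis = axis, L = L, area = area)
}

#' Equivalent Young's modulus of a cell mesh
#'
#' Homogenized initial-slope modulus under uniaxial-stress compression:
#' equivalent stress is the face reaction resultant divided by the
#' projected cell area, equivalent strain the face displacement divided by
#' the cell length.
#'
#' @param mesh A cell [voxel_mesh()].
#' @param material A [material_linear()] (for a superelastic cell the
#'   initial slope is the austenite branch; pass
#'   `material_linear(params$E_A, params$nu)`).
#' @param strain Probe strain (default 0.1%, inside the elastic branch).
#' @param axis Loading axis.
#' @param ... Passed to [fe_solve_linear()].
#' @return Equivalent modulus (GPa).
#' @export
equivalent_modulus <- function(mesh, material, strain = 1e-3, axis = 3, ...) {
  bc <- cell_uniaxial_bc(mesh, strain, axis)
  res <- fe_solve_linear(mesh, list(material), bc$fix, ...)
  Fz <- sum(res$reactions[3 * (bc$top - 1) + axis])
  (abs(Fz) / bc$area) / strain / 1e3
}

#' Homogenized equivalent stress-strain curve of a unit cell
#'
#' Drives the cell in uniaxial-stress compression and reports the
#' macroscopic (equivalent) curve together with the local stress extrema:
#' equivalent stress = reaction / projected area, equivalent strain =
#' face displacement / cell length.  For a linear material one solve is
#' scaled; for the superelastic model the incremental solver is used.
#'
#' @param mesh A cell [voxel_mesh()].
#' @param material [material_linear()] or [sma_params()].
#' @param max_strain Final equivalent compressive strain (default 2%).
#' @param increments Load increments for the superelastic path.
#' @param axis Loading axis.
#' @param porosity Optional porosity annotation.
#' @param ... Passed to the solver.
#' @return An `equivalent_response`: data frame-like list with `strain`,
#'   `stress` (MPa, compression positive), per-step raw and filtered max
#'   local von Mises (MPa), and the equivalent modulus (GPa).
#' @export
equivalent_curve <- function(mesh, material, max_strain = 0.02,
                             increments = 8, axis = 3, porosity = NA_real_,
                             ...) {
  bc <- cell_uniaxial_bc(mesh, max_strain, axis)
  if (inherits(material, "linear_material")) {
    res <- fe_solve_linear(mesh, list(material), bc$fix, ...)
    Fz <- abs(sum(res$reactions[3 * (bc$top - 1) + axis]))
    s_eq <- Fz / bc$area
    fr <- seq(1 / increments, 1, length.out = increments)
    out <- list(strain = fr * max_strain, stress = fr * s_eq,
                vm_max = fr * max(res$vm),
                vm_max_filtered = fr * filtered_max(res$vm),
                vm_peak = fr * cusp_filtered_peak(res$vm),
                modulus = (s_eq / max_strain) / 1e3,
                vm = res$vm, porosity = porosity,
                material = material$name)
  } else if (inherits(material, "sma_params")) {
    trk <- bc_fix(bc$top, axis, 0)
    sol <- fe_solve_sma(mesh, material, bc$fix, n_increments = increments,
                        track = trk, ...)
    st <- sol$steps
    stress <- abs(st$reaction) / bc$area
    strain <- st$lambda * max_strain
    out <- list(strain = strain, stress = stress,
                vm_max = st$vm_max, vm_max_filtered = st$vm_max_filtered,
                vm_peak = st$vm_peak,
                modulus = (stress[1] / strain[1]) / 1e3,
                vm = sol$vm, xi = sol$xi, porosity = porosity,
                material = "NiTi superelastic")
  } else {
    stop("material must be a linear_material or sma_params")
  }
  structure(out, class = "equivalent_response")
}

#' @export
print.equivalent_response <- function(x, ...) {
  cat(sprintf("Equivalent response (%s): modulus %.2f GPa, porosity %s\n",
              x$material, x$modulus,
              ifelse(is.na(x$porosity), "?", sprintf("%.3f", x$porosity))))
  cat(sprintf("  final: strain %.3f%%, stress %.1f MPa, max local vM %.0f MPa\n",
              100 * max(x$strain), max(x$stress), max(x$vm_max)))
  invisible(x)
}

#' Local stress amplification report at a given equivalent strain
#'
#' Reports the maximum element-centroid von Mises stress among the solid
#' elements of a porous cell at the requested equivalent strain, the
#' amplification factor relative to the equivalent (macroscopic) stress,
#' and whether the material yield strength is exceeded.  The
#' corner-singularity filter (drop the single highest element when it
#' exceeds three times the runner-up) is applied to the filtered value;
#' both raw and filtered maxima are returned.
#'
#' @param response An [equivalent_curve()] result.
#' @param at_strain Equivalent strain at which to report (must lie within
#'   the computed range).
#' @param sigma_y Yield strength (MPa) used for the exceedance flag.
#' @param measure Peak measure used for the amplification and yield flag:
#'   `"cusp"` (mesh-stable [cusp_filtered_peak()], default), `"filtered"`
#'   (single-element corner filter) or `"raw"`.  All three values are
#'   returned regardless.
#' @return List: `max_vm` (selected measure, MPa), `max_vm_raw`,
#'   `max_vm_filtered`, `max_vm_cusp` (MPa), `eq_stress` (MPa),
#'   `amplification`, `exceeds_yield`.
#' @export
local_stress_report <- function(response, at_strain = 0.02, sigma_y,
                                measure = c("cusp", "filtered", "raw")) {
  measure <- match.arg(measure)
  s <- response$strain
  if (at_strain > max(s) + 1e-12 || at_strain < min(s) - 1e-12) {
    stop(sprintf("requested strain %.4f outside computed range [%.4f, %.4f]",
                 at_strain, min(s), max(s)))
  }
  at <- function(y) approx(s, y, xout = at_strain, rule = 2)$y
  vmf <- at(response$vm_max_filtered)
  vmr <- at(response$vm_max)
  vmc <- at(response$vm_peak)
  se <- at(response$stress)
  vm <- switch(measure, cusp = vmc, filtered = vmf, raw = vmr)
  list(max_vm = vm, max_vm_raw = vmr, max_vm_filtered = vmf,
       max_vm_cusp = vmc, eq_stress = se,
       amplification = vm / se, exceeds_yield = vm > sigma_y,
       sigma_y = sigma_y, measure = measure)
}

#' Porosity versus equivalent modulus sweep
#'
#' Homogenizes the tri-cylinder cell family (fixed pore diameter, edge
#' length solved per porosity) across a porosity grid.
#'
#' @param material [material_linear()] or [sma_params()] (initial-slope
#'   modulus uses the austenite branch).
#' @param porosities Porosity grid in the attainable range.
#' @param d Pore diameter (mm).
#' @param resolution Voxels per cell edge.
#' @param bc Homogenization family: `"periodic"` (tiled-lattice estimate)
#'   or `"uniaxial"` (isolated compression sample).
#' @param ... Passed to the homogenizer.
#' @return Data frame with `porosity`, `a` (mm), `modulus` (GPa).
#' @export
porosity_modulus_sweep <- function(material, porosities, d = 1,
                                   resolution = 32,
                                   bc = c("periodic", "uniaxial"), ...) {
  bc <- match.arg(bc)
  if (inherits(material, "sma_params")) {
    material <- material_linear(material$E_A, material$nu, material$sigma_y,
                                "NiTi (austenite)")
  }
  rows <- lapply(porosities, function(p) {
    if (p <= 0) {
      return(data.frame(porosity = 0, a = NA_real_, modulus = material$E))
    }
    cell <- solve_cell_for_porosity(d, p)
    mesh <- voxelize_unit_cell(cell, resolution)
    E <- if (bc == "periodic") {
      periodic_cell_stiffness(mesh, material, ...)$E
    } else {
      equivalent_modulus(mesh, material, ...)
    }
    data.frame(porosity = p, a = cell$a, modulus = E)
  })
  do.call(rbind, rows)
}
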