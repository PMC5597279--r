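#' Stiffness-matching design specification
#'
#' @param target_modulus Target equivalent Young's modulus (GPa); the
#'   default 12 GPa is the estimated average modulus of mandibular
#'   cortical bone in the molar region.
#' @param material [material_linear()] or [sma_params()] of the dense
#'   plate material.
#' @param d Pore cylinder diameter (mm).
#' @param shell Dense shell thickness for plate solids (mm).
#' @param safety_strain Equivalent strain at which local stresses are
#'   checked (default 2%, the strain recoverable by cortical bone).
#' @return A `design_spec` object.
#' @export
design_spec <- function(target_modulus = 12, material = sma_params(),
                        d = 1, shell = 0.2, safety_strain = 0.02) {
  dense <- if (inherits(material, "sma_params")) material$E_A else material$E
  if (!(target_modulus > 0 && target_modulus < dense)) {
    stop(sprintf("target modulus must lie in (0, %g) GPa", dense))
  }
  structure(list(target_modulus = target_modulus, material = material,
                 d = d, shell = shell, safety_strain = safety_strain,
                 dense_modulus = dense),
            class = "design_spec")
}

#' Solve the porosity that matches a target equivalent modulus
#'
#' Root-finding on the strictly monotone porosity-modulus map of the
#' tri-cylinder cell family: a relative-density power-law estimate seeds
#' the search, a bracket is established by direct FE homogenizations, and
#' safeguarded secant (regula falsi) iterations refine the porosity until
#' the homogenized modulus is within `tol` of the target.
#'
#' @param spec A [design_spec()].
#' @param resolution Voxels per cell edge for the homogenizations.
#' @param tol Modulus tolerance (GPa).
#' @param max_iter Iteration cap.
#' @param bc Homogenization family: `"periodic"` (default; the estimate
#'   for a cell inside a tiled plate, see [periodic_cell_stiffness()]) or
#'   `"uniaxial"` (isolated compression sample, [equivalent_modulus()]).
#' @param ... Passed to the homogenizer.
#' @return List: `porosity`, `cell` ([unit_cell()]), `modulus` (GPa,
#'   achieved), `history` (data frame of iterates).
#' @export
solve_porosity_for_modulus <- function(spec, resolution = 64, tol = 0.1,
                                       max_iter = 15,
                                       bc = c("periodic", "uniaxial"), ...) {
  stopifnot(inherits(spec, "design_spec"))
  bc <- match.arg(bc)
  mat <- spec$material
  if (inherits(mat, "sma_params")) {
    mat <- material_linear(mat$E_A, mat$nu, mat$sigma_y, "austenite")
  }
  Ed <- spec$dense_modulus
  target <- spec$target_modulus
  modulus_at <- function(p) {
    cell <- solve_cell_for_porosity(spec$d, p)
    mesh <- voxelize_unit_cell(cell, resolution)
    if (bc == "periodic") {
      periodic_cell_stiffness(mesh, mat, ...)$E
    } else {
      equivalent_modulus(mesh, mat, ...)
    }
  }
  hist <- data.frame(porosity = numeric(0), modulus = numeric(0))
  note <- function(p, m) hist <<- rbind(hist, data.frame(porosity = p, modulus = m))

  # Gibson-Ashby style seed: E/Ed ~ (1 - p)^2
  p <- min(max(1 - sqrt(target / Ed), 0.05), 0.9)
  m <- modulus_at(p); note(p, m)
  step <- 0.08
  plo <- phi <- NULL  # bracket: modulus(plo) > target > modulus(phi)
  if (m > target) { plo <- p; mlo <- m } else { phi <- p; mhi <- m }
  while ((is.null(plo) || is.null(phi)) && nrow(hist) < max_iter) {
    p <- min(max(p + ifelse(m > target, step, -step), 0.02), 0.94)
    m <- modulus_at(p); note(p, m)
    if (m > target) { plo <- p; mlo <- m } else { phi <- p; mhi <- m }
    step <- step * 1.5
  }
  if (is.null(plo) || is.null(phi)) {
    stop("could not bracket the target modulus: target may be unattainable")
  }
  # at fixed voxel resolution the homogenized modulus is piecewise constant
  # in porosity; stop once the bracket is below that granularity
  gran <- 0.15 / resolution
  while (abs(m - target) > tol && phi - plo > gran &&
         nrow(hist) < max_iter) {
    p_sec <- plo + (mlo - target) * (phi - plo) / (mlo - mhi)
    p <- min(max(p_sec, plo + gran / 2), phi - gran / 2)
    m <- modulus_at(p); note(p, m)
    if (m %in% hist$modulus[-nrow(hist)]) {
      # identical voxel geometry: fall back to a bisection step
      p <- (plo + phi) / 2
      m <- modulus_at(p); note(p, m)
    }
    if (m > target) { plo <- p; mlo <- m } else { phi <- p; mhi <- m }
  }
  best <- which.min(abs(hist$modulus - target))
  p <- hist$porosity[best]
  list(porosity = p, cell = solve_cell_for_porosity(spec$d, p),
       modulus = hist$modulus[best], resolution = resolution,
       history = hist)
}

#' Local-stress safety check of a porous design
#'
#' Drives the designed cell to the safety strain and compares the maximum
#' local von Mises stress (corner-singularity filtered) against the
#' material yield strength.  For the superelastic material the full
#' incremental response is used; within this model local strains are
#' recoverable whenever the stress stays below yield (no plasticity),
#' so the pass flag is the yield criterion.
#'
#' @param cell A [unit_cell()] (e.g. from [solve_porosity_for_modulus()]).
#' @param material [material_linear()] with `sigma_y`, or [sma_params()].
#' @param safety_strain Equivalent strain for the check.
#' @param resolution Voxels per cell edge.
#' @param increments Increments for the superelastic path.
#' @param ... Passed to [equivalent_curve()].
#' @return List: `max_stress` (MPa), `safety_factor`, `pass`, and the
#'   underlying `report` from [local_stress_report()].
#' @export
safety_check <- function(cell, material, safety_strain = 0.02,
                         resolution = 24, increments = 8, ...) {
  mesh <- voxelize_unit_cell(cell, resolution)
  sy <- if (inherits(material, "sma_params")) material$sigma_y else material$sigma_y
  if (is.na(sy)) stop("material has no yield strength defined")
  resp <- equivalent_curve(mesh, material, max_strain = safety_strain,
                           increments = increments,
                           porosity = porosity_analytic(cell), ...)
  rep <- local_stress_report(resp, at_strain = safety_strain, sigma_y = sy)
  factor <- sy / rep$max_vm
  list(max_stress = rep$max_vm, safety_factor = factor,
       pass = factor > 1, report = rep, response = resp)
}

#' Full stiffness-matching design report
#'
#' Runs the porosity selection loop and the safety check and collects a
#' JSON-serializable report: porosity, cell dimensions, achieved modulus,
#' maximum local stress, safety factor and pass/fail.
#'
#' @inheritParams solve_porosity_for_modulus
#' @param safety_resolution Cell resolution for the safety check.
#' @param ... Passed to the solvers.
#' @return A list report.
#' @export
design_report <- function(spec, resolution = 64, safety_resolution = 24,
                          tol = 0.1, bc = "periodic", ...) {
  sel <- solve_porosity_for_modulus(spec, resolution = resolution, tol = tol,
                                    bc = bc)
  saf <- safety_check(sel$cell, spec$material,
                      safety_strain = spec$safety_strain,
                      resolution = safety_resolution, ...)
  list(material = if (inherits(spec$material, "sma_params"))
         "NiTi superelastic" else spec$material$name,
       target_modulus_GPa = spec$target_modulus,
       dense_modulus_GPa = spec$dense_modulus,
       porosity = sel$porosity,
       porosity_percent = 100 * sel$porosity,
       pore_diameter_mm = spec$d,
       cell_edge_mm = sel$cell$a,
       achieved_modulus_GPa = sel$modulus,
       safety_strain = spec$safety_strain,
       max_local_stress_MPa = saf$max_stress,
       safety_factor = saf$safety_factor,
       pass = saf$pass)
}
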