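#' Porous fixation plate solid
#'
#' Parametric plate: a box of `length x width x thickness` mm (mesiodistal
#' x superoinferior x buccolingual), filled with the tiled tri-cylinder
#' pore lattice, wrapped in a fully dense shell that smooths the edges,
#' and pierced by through-thickness screw holes.
#'
#' Axis convention for a standalone plate mesh: x = length, y = thickness,
#' z = width.
#'
#' @param length,width,thickness Plate dimensions (mm); the inferior
#'   mandible bar is 78 x 4 x 1.5, the superior mini-plates 18 x 2.8 x 1.
#' @param cell [unit_cell()] of the pore lattice (ignored when `NULL`:
#'   dense plate).
#' @param shell Dense shell thickness (mm, default 0.2).
#' @param screw_x Screw hole axial positions along the length (mm);
#'   holes run through the thickness.
#' @param screw_z Screw hole positions across the width (mm); recycled
#'   against `screw_x`.
#' @param screw_diameter Hole diameter (mm, default 1.4).
#' @return A `plate_solid` object.
#' @export
plate_solid <- function(length, width, thickness, cell = NULL, shell = 0.2,
                        screw_x = numeric(0), screw_z = width / 2,
                        screw_diameter = 1.4) {
  stopifnot(length > 0, width > 0, thickness > 0, shell >= 0)
  if (!is.null(cell)) stopifnot(inherits(cell, "unit_cell"))
  screw_z <- rep_len(screw_z, base::length(screw_x))
  structure(list(length = length, width = width, thickness = thickness,
                 cell = cell, shell = shell,
                 screw_x = screw_x, screw_z = screw_z,
                 screw_diameter = screw_diameter),
            class = "plate_solid")
}

#' Voxelize a fixation plate
#'
#' Voxel centres inside a tiled pore cylinder are void unless they lie in
#' the dense shell; screw holes are void regardless.  Interior and
#' whole-plate porosities are attached as attributes (the shell lowers the
#' whole-plate value below the unit-cell porosity).
#'
#' @param plate A [plate_solid()].
#' @param h Voxel edge length (mm, scalar).
#' @return A [voxel_mesh()] with attributes `porosity_interior` and
#'   `porosity_whole`.
#' @export
build_plate <- function(plate, h) {
  stopifnot(inherits(plate, "plate_solid"), h > 0)
  if (!is.null(plate$cell) && plate$cell$d > 0) {
    strut <- (plate$cell$a - plate$cell$d) / h
    if (strut < 4) {
      stop(sprintf(paste0("under-resolved geometry: %.1f voxels across the ",
                          "thinnest ligament (need >= 4); reduce h"), strut))
    }
  }
  nx <- max(1L, round(plate$length / h))
  ny <- max(1L, round(plate$thickness / h))
  nz <- max(1L, round(plate$width / h))
  x <- (seq_len(nx) - 0.5) * h
  y <- (seq_len(ny) - 0.5) * h
  z <- (seq_len(nz) - 0.5) * h
  X <- array(rep(x, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(y, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), dim = c(nx, ny, nz))

  pore <- array(FALSE, dim = c(nx, ny, nz))
  if (!is.null(plate$cell) && plate$cell$d > 0) {
    a <- plate$cell$a
    r2 <- (plate$cell$d / 2)^2
    cx <- (X %% a) - a / 2
    cy <- (Y %% a) - a / 2
    cz <- (Z %% a) - a / 2
    pore <- (cy^2 + cz^2 < r2) | (cx^2 + cz^2 < r2) | (cx^2 + cy^2 < r2)
  }
  sh <- plate$shell
  shell_mask <- (X < sh) | (X > plate$length - sh) |
    (Y < sh) | (Y > plate$thickness - sh) |
    (Z < sh) | (Z > plate$width - sh)
  solid <- !pore | shell_mask
  if (length(plate$screw_x) > 0) {
    rs2 <- (plate$screw_diameter / 2)^2
    for (s in seq_along(plate$screw_x)) {
      hole <- (X - plate$screw_x[s])^2 + (Z - plate$screw_z[s])^2 < rs2
      solid <- solid & !hole
    }
  }
  mesh <- voxel_mesh(array(as.integer(solid), dim = dim(solid)), h = h)
  interior <- !shell_mask
  attr(mesh, "porosity_interior") <- 1 - sum(solid & interior) / sum(interior)
  attr(mesh, "porosity_whole") <- 1 - mean(solid)
  mesh
}
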