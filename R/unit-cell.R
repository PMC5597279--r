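#' Tri-cylinder pore unit cell
#'
#' The porous lattice motif: three orthogonal cylinders of equal diameter
#' `d` intersecting at the centre of a cube of edge `a`.  Under the
#' default `"void"` convention the cylinders are pore channels, so the
#' cell porosity is the volume fraction of the cylinder union; the
#' `"strut"` convention (cylinders are material) is the complementary
#' reading.
#'
#' @param d Pore cylinder diameter (mm), `0 <= d <= a`.
#' @param a Cell edge length (mm).
#' @param convention `"void"` (default) or `"strut"`.
#' @return A `unit_cell` object.
#' @examples
#' porosity_analytic(unit_cell(d = 1, a = 1))   # 0.942
#' @export
unit_cell <- function(d, a, convention = c("void", "strut")) {
  convention <- match.arg(convention)
  stopifnot(a > 0, d >= 0)
  if (d > a) stop("pore diameter d exceeds the cell edge a: cylinders protrude")
  structure(list(d = d, a = a, convention = convention), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Tri-cylinder unit cell: d = %g mm, a = %g mm (%s convention)\n",
              x$d, x$a, x$convention))
  cat(sprintf("  analytic porosity = %.4f\n", porosity_analytic(x)))
  invisible(x)
}

#' Analytic porosity of the tri-cylinder cell
#'
#' Inclusion-exclusion over the three orthogonal cylinders of radius d/2
#' and length `a`, using the Steinmetz intersection volumes
#' (bicylinder `16 r^3 / 3`, tricylinder `8 (2 - sqrt(2)) r^3`):
#' `V = 3 pi r^2 a - 3 (16/3) r^3 + 8 (2 - sqrt(2)) r^3`.  The porosity is
#' `V / a^3` under the void convention and its complement otherwise.
#'
#' @param cell A [unit_cell()].
#' @return Void fraction in `[0, 1]`.
#' @export
porosity_analytic <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  r <- cell$d / 2
  v <- 3 * pi * r^2 * cell$a - 16 * r^3 + 8 * (2 - sqrt(2)) * r^3
  frac <- v / cell$a^3
  if (cell$convention == "void") frac else 1 - frac
}

# Indicator of the cylinder union on voxel centres; returns a logical
# nx x ny x nz array, TRUE where inside a cylinder.
cylinder_union_indicator <- function(cell, resolution) {
  a <- cell$a
  r2 <- (cell$d / 2)^2
  x <- (seq_len(resolution) - 0.5) * a / resolution - a / 2
  d2 <- outer(x^2, x^2, "+")                       # squared radial distances
  # cylinder along x occupies (y, z) with d2 < r2; d2 is symmetric, so the
  # permutations below give the y- and z-aligned cylinders
  cyl_x <- array(rep(d2 < r2, each = resolution), dim = rep(resolution, 3))
  cyl_y <- aperm(cyl_x, c(2, 1, 3))                # cylinder along y: x-z
  cyl_z <- aperm(cyl_x, c(3, 2, 1))                # cylinder along z: x-y
  cyl_x | cyl_y | cyl_z
}

#' Voxelized porosity of the tri-cylinder cell
#'
#' Discretization oracle for [porosity_analytic()]: the cell is sampled on
#' a cubic grid of voxel centres and the void fraction counted.
#'
#' @param cell A [unit_cell()].
#' @param resolution Voxels per cell edge (at least 8).
#' @return Void fraction.
#' @export
porosity_voxel <- function(cell, resolution) {
  stopifnot(inherits(cell, "unit_cell"), resolution >= 8)
  pore <- cylinder_union_indicator(cell, resolution)
  frac <- mean(pore)
  if (cell$convention == "void") frac else 1 - frac
}

#' Solve the cell edge length for a target porosity at fixed pore diameter
#'
#' The analytic porosity is strictly decreasing in `a` at fixed `d`;
#' bisection recovers the edge length realizing a requested porosity.
#'
#' @param d Pore diameter (mm).
#' @param target_porosity Requested void fraction in `(0, porosity(d = a)]`.
#' @param convention Passed to [unit_cell()].
#' @return A [unit_cell()] whose analytic porosity matches the target to
#'   within 1e-6.
#' @export
solve_cell_for_porosity <- function(d, target_porosity, convention = "void") {
  stopifnot(d > 0)
  if (target_porosity <= 0 || target_porosity > 1) {
    stop("target porosity must lie in (0, 1]")
  }
  pmax_ <- porosity_analytic(unit_cell(d, d, convention))
  if (target_porosity > pmax_ + 1e-12) {
    stop(sprintf("target porosity %.4f unattainable at d = %g (max %.4f at a = d)",
                 target_porosity, d, pmax_))
  }
  f <- function(a) porosity_analytic(unit_cell(d, a, convention)) - target_porosity
  hi <- d
  lo <- d * 50
  while (f(lo) > 0) lo <- lo * 4   # porosity -> 0 as a grows
  a <- uniroot(f, c(hi, lo), tol = 1e-12)$root
  unit_cell(d, a, convention)
}

#' Solve the pore diameter for a target porosity at fixed cell edge
#'
#' Dual of [solve_cell_for_porosity()]: porosity is strictly increasing in
#' `d` at fixed `a`.
#'
#' @param a Cell edge length (mm).
#' @param target_porosity Requested void fraction in `[0, porosity(d = a)]`.
#' @param convention Passed to [unit_cell()].
#' @return A [unit_cell()].
#' @export
solve_diameter_for_porosity <- function(a, target_porosity,
                                        convention = "void") {
  stopifnot(a > 0, target_porosity >= 0, target_porosity <= 1)
  if (target_porosity == 0) return(unit_cell(0, a, convention))
  pmax_ <- porosity_analytic(unit_cell(a, a, convention))
  if (target_porosity > pmax_ + 1e-12) {
    stop(sprintf("target porosity %.4f unattainable at a = %g (max %.4f at d = a)",
                 target_porosity, a, pmax_))
  }
  f <- function(d) porosity_analytic(unit_cell(d, a, convention)) - target_porosity
  d <- uniroot(f, c(0, a), tol = 1e-12)$root
  unit_cell(d, a, convention)
}

#' Voxelize a unit cell into a hexahedral mesh
#'
#' Cell-centred, axis-aligned voxels with zero origin.  Solid voxels carry
#' material tag 1; pore voxels are void.
#'
#' @param cell A [unit_cell()].
#' @param resolution Voxels per edge.  Must leave at least 4 voxels across
#'   the thinnest solid ligament (`a - d` for the void convention).
#' @return A [voxel_mesh()].
#' @export
voxelize_unit_cell <- function(cell, resolution) {
  stopifnot(inherits(cell, "unit_cell"), resolution >= 2)
  if (cell$convention == "void" && cell$d > 0 && cell$d < cell$a) {
    strut <- (cell$a - cell$d) * resolution / cell$a
    if (strut < 4) {
      stop(sprintf(paste0("under-resolved geometry: %.1f voxels across the ",
                          "thinnest ligament (need >= 4); increase resolution"),
                   strut))
    }
  }
  pore <- cylinder_union_indicator(cell, resolution)
  solid <- if (cell$convention == "void") !pore else pore
  voxel_mesh(array(as.integer(solid), dim = dim(pore)),
             h = rep(cell$a / resolution, 3))
}
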