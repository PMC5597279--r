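# Periodic homogenization of the unit cell.
#
# The displacement is split as u = E x + w with w periodic; the affine
# part enters as a constant-strain load and the fluctuation is solved on
# the periodically wrapped node set.  The tri-cylinder cell has cubic
# symmetry, so a single macroscopic strain solve (e_zz = 1) yields C11,
# C12 and hence the effective Young's modulus.

# Wrap the node numbering across opposite faces.
periodic_edof <- function(mesh) {
  dm <- mesh$dim
  nx1 <- dm[1] + 1L
  ny1 <- dm[2] + 1L
  gid <- mesh$node_gid
  gi <- gid %% nx1
  gj <- (gid %/% nx1) %% ny1
  gk <- gid %/% (nx1 * ny1)
  wg <- (gi %% dm[1]) + nx1 * (gj %% dm[2]) + nx1 * ny1 * (gk %% dm[3])
  uw <- unique(wg)
  pn <- match(wg, uw)
  edof <- matrix(0L, 24, nrow(mesh$conn))
  for (l in 1:8) {
    base <- 3L * (pn[mesh$conn[, l]] - 1L)
    edof[3 * l - 2, ] <- base
    edof[3 * l - 1, ] <- base + 1L
    edof[3 * l, ] <- base + 2L
  }
  list(edof = edof, nnod = length(uw))
}

#' Periodic effective stiffness of a unit cell
#'
#' Periodic homogenization under a prescribed macroscopic strain: the cell
#' is wrapped across opposite faces, the periodic fluctuation field is
#' solved for a unit axial macro strain, and the macroscopic stress is
#' volume-averaged.  Cubic symmetry of the tri-cylinder cell turns the
#' single solve into the full cubic stiffness (`C11`, `C12`) and the
#' effective Young's modulus `E = (C11 - C12)(C11 + 2 C12)/(C11 + C12)`.
#'
#' This is the estimate appropriate for the interior of a plate tiled with
#' identical cells; the uniaxial-stress single-cell family
#' ([equivalent_modulus()]) emulates an isolated compression sample whose
#' cut surface struts make it softer, especially at high porosity.
#'
#' @param mesh A cell [voxel_mesh()] (periodic geometry, single material).
#' @param material A [material_linear()].
#' @param cg_tol,cg_maxit Solver controls.
#' @return List: `E` (GPa), `C11`, `C12` (GPa), solver iterations.
#' @export
periodic_cell_stiffness <- function(mesh, material, cg_tol = 1e-8,
                                    cg_maxit = NULL) {
  pe <- periodic_edof(mesh)
  ndof <- 3L * pe$nnod
  nel <- nrow(mesh$elem_ijk)
  D <- material$D
  ke <- hex_ke_cpp(D, mesh$h[1], mesh$h[2], mesh$h[3])
  kes <- matrix(as.vector(ke), 576, 1)
  keidx <- rep(0L, nel)
  BL <- hex_B_cpp(mesh$h[1], mesh$h[2], mesh$h[3])
  V <- prod(mesh$h)
  Emac <- c(0, 0, 1, 0, 0, 0)
  # constant-strain load of the affine part: f_e = -V B' D Emac
  fe <- -V * crossprod(BL$Bc, D %*% Emac)
  f <- numeric(ndof)
  for (l in 1:24) {
    # identical load per element at local slot l: weight by dof multiplicity
    f <- f + fe[l] * tabulate(pe$edof[l, ] + 1L, nbins = ndof)
  }
  # pin one node (periodicity leaves only translations)
  freemask <- rep(1, ndof)
  freemask[1:3] <- 0
  sp <- empty_springs()
  if (is.null(cg_maxit)) cg_maxit <- max(2000L, 30L * ceiling(sqrt(ndof)))
  sol <- ebe_pcg_cpp(pe$edof, keidx, kes, sp, f, freemask, numeric(ndof),
                     cg_tol, cg_maxit)
  if (!sol$converged) {
    warning(sprintf("periodic CG stopped at relres %.2e", sol$relres))
  }
  # macroscopic stress: volume average over the cell bounding box
  st <- linear_stress_cpp(pe$edof, sol$u, matrix(as.vector(D), 36, 1),
                          keidx, matrix(0, 6, 0),
                          mesh$h[1], mesh$h[2], mesh$h[3])
  Vtot <- prod(mesh$dim) * V
  sig_bar <- (rowSums(st$sigma) + nel * as.vector(D %*% Emac)) * V / Vtot
  C11 <- sig_bar[3] / 1e3
  C12 <- mean(sig_bar[1:2]) / 1e3
  E <- (C11 - C12) * (C11 + 2 * C12) / (C11 + C12)
  list(E = E, C11 = C11, C12 = C12, iters = sol$iters)
}
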