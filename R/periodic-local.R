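# Local stress field of a cell inside a large tiled sample under
# macroscopic uniaxial stress (linear materials).
#
# One periodic solve at unit axial macro strain gives the field S3; the
# cubic symmetry of the tri-cylinder cell yields the lateral-strain
# response fields S1, S2 as axis permutations of S3.  Superposing with
# the lateral macro strain that annuls the mean lateral stress gives the
# interior field of a sample compressed to a given equivalent strain with
# stress-free sides.

# element-id volume array for permutation mapping
element_id_volume <- function(mesh) {
  vol <- array(0L, mesh$dim)
  vol[mesh$elem_lin] <- seq_len(nrow(mesh$elem_ijk))
  vol
}

#' Interior local stress of a tiled cell under uniaxial macroscopic stress
#'
#' @param mesh A cubic cell [voxel_mesh()] (equal grid dimensions; the
#'   tri-cylinder cell qualifies).
#' @param material A [material_linear()].
#' @param eq_strain Macroscopic axial compressive strain (positive).
#' @param cg_tol Solver tolerance.
#' @return List: `vm` (per-element von Mises, MPa), `max_vm`
#'   (corner-singularity filtered), `max_vm_raw`, `eq_stress` (MPa),
#'   `modulus` (GPa), `amplification`.
#' @export
periodic_local_stress <- function(mesh, material, eq_strain = 0.02,
                                  cg_tol = 1e-8) {
  stopifnot(length(unique(mesh$dim)) == 1L)
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
  fe <- -V * crossprod(BL$Bc, D %*% Emac)
  f <- numeric(ndof)
  for (l in 1:24) {
    f <- f + fe[l] * tabulate(pe$edof[l, ] + 1L, nbins = ndof)
  }
  freemask <- rep(1, ndof)
  freemask[1:3] <- 0
  sol <- ebe_pcg_cpp(pe$edof, keidx, kes, empty_springs(), f, freemask,
                     numeric(ndof), cg_tol,
                     max(2000L, 30L * ceiling(sqrt(ndof))))
  st <- linear_stress_cpp(pe$edof, sol$u, matrix(as.vector(D), 36, 1),
                          keidx, matrix(0, 6, 0),
                          mesh$h[1], mesh$h[2], mesh$h[3])
  S3 <- st$sigma + as.vector(D %*% Emac)   # field for unit e_zz

  # macro stiffness entries from the volume average
  Vtot <- prod(mesh$dim) * V
  sig_bar <- rowSums(S3) * V / Vtot
  C11 <- sig_bar[3]
  C12 <- mean(sig_bar[1:2])

  # permute S3 into the unit e_xx and e_yy response fields
  vol <- element_id_volume(mesh)
  # e_xx response: swap axes x<->z in space and in tensor components
  perm_xz <- as.vector(aperm(vol, c(3, 2, 1)))[mesh$elem_lin]
  S1 <- S3[c(3, 2, 1, 5, 4, 6), perm_xz]
  # e_yy response: swap axes y<->z
  perm_yz <- as.vector(aperm(vol, c(1, 3, 2)))[mesh$elem_lin]
  S2 <- S3[c(1, 3, 2, 6, 5, 4), perm_yz]

  # lateral macro strain for stress-free sides, compression along z
  ea <- -eq_strain
  el <- -C12 * ea / (C11 + C12)
  S <- ea * S3 + el * (S1 + S2)
  vm <- sqrt(pmax(0,
    0.5 * ((S[1, ] - S[2, ])^2 + (S[2, ] - S[3, ])^2 + (S[3, ] - S[1, ])^2) +
      3 * (S[4, ]^2 + S[5, ]^2 + S[6, ]^2)))
  eq_stress <- abs(ea * C11 + 2 * el * C12)
  Eeff <- (C11 - C12) * (C11 + 2 * C12) / (C11 + C12) / 1e3
  list(vm = vm, max_vm = filtered_max(vm), max_vm_raw = max(vm),
       eq_stress = eq_stress, modulus = Eeff,
       amplification = filtered_max(vm) / eq_stress)
}
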