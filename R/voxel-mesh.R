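#' Voxel hexahedral mesh
#'
#' Regular, axis-aligned hexahedral discretization of a solid/void
#' indicator field.  Each voxel carries an integer material tag (0 = void)
#' and optionally a contact group: nodes are shared between neighbouring
#' solid voxels of the same group, while coincident nodes of different
#' groups are duplicated so that interface springs (ties or
#' compression-only contact) can couple them.
#'
#' @param tag Integer array `nx x ny x nz`; 0 marks void, positive values
#'   are material ids.
#' @param h Voxel edge lengths (mm), scalar or length 3.
#' @param grp Optional integer array of contact groups (default all 1).
#' @param origin Coordinates of the grid corner (mm).
#' @return A `voxel_mesh` object with the element table, node coordinates
#'   and the dof map.
#' @export
voxel_mesh <- function(tag, h, grp = NULL, origin = c(0, 0, 0)) {
  stopifnot(length(dim(tag)) == 3L)
  if (length(h) == 1L) h <- rep(h, 3)
  dm <- dim(tag)
  if (is.null(grp)) grp <- array(1L, dm)
  sel <- which(tag != 0L)
  if (length(sel) == 0L) stop("mesh has no solid voxels")
  ijk <- arrayInd(sel, dm)
  nel <- nrow(ijk)
  ngrp <- max(grp)
  nx1 <- dm[1] + 1L; ny1 <- dm[2] + 1L
  ge <- grp[sel]

  # corner grid ids for local nodes l = di + 2 dj + 4 dk (0-based)
  keys <- matrix(0, nel, 8)
  for (l in 0:7) {
    di <- bitwAnd(l, 1L)
    dj <- bitwAnd(bitwShiftR(l, 1L), 1L)
    dk <- bitwAnd(bitwShiftR(l, 2L), 1L)
    gid <- (ijk[, 1] - 1 + di) + nx1 * (ijk[, 2] - 1 + dj) +
      nx1 * ny1 * (ijk[, 3] - 1 + dk)
    keys[, l + 1] <- gid * ngrp + (ge - 1)
  }
  uk <- sort(unique(as.vector(keys)))
  conn <- matrix(match(keys, uk), nel, 8)
  node_gid <- uk %/% ngrp
  node_grp <- as.integer(uk %% ngrp) + 1L
  gi <- node_gid %% nx1
  gj <- (node_gid %/% nx1) %% ny1
  gk <- node_gid %/% (nx1 * ny1)
  node_xyz <- cbind(origin[1] + gi * h[1], origin[2] + gj * h[2],
                    origin[3] + gk * h[3])

  edof <- matrix(0L, 24, nel)
  for (l in 1:8) {
    base <- 3L * (conn[, l] - 1L)
    edof[3 * l - 2, ] <- base
    edof[3 * l - 1, ] <- base + 1L
    edof[3 * l, ] <- base + 2L
  }

  structure(list(dim = dm, h = h, origin = origin,
                 elem_ijk = ijk, elem_lin = sel,
                 matid = as.integer(tag[sel]), grp_e = as.integer(ge),
                 conn = conn, edof = edof,
                 nnodes = length(uk), ndof = 3L * length(uk),
                 node_xyz = node_xyz, node_gid = node_gid,
                 node_grp = node_grp),
            class = "voxel_mesh")
}

#' @export
print.voxel_mesh <- function(x, ...) {
  cat(sprintf("Voxel mesh: %d x %d x %d grid, h = (%g, %g, %g) mm\n",
              x$dim[1], x$dim[2], x$dim[3], x$h[1], x$h[2], x$h[3]))
  cat(sprintf("  %d solid elements, %d nodes, %d dofs, solid volume %.3f mm^3\n",
              nrow(x$elem_ijk), x$nnodes, x$ndof, mesh_solid_volume(x)))
  invisible(x)
}

#' Total solid volume of a mesh (mm^3)
#' @param mesh A [voxel_mesh()].
#' @export
mesh_solid_volume <- function(mesh) {
  nrow(mesh$elem_ijk) * prod(mesh$h)
}

#' Solid volume fraction of the bounding grid
#' @param mesh A [voxel_mesh()].
#' @export
mesh_solid_fraction <- function(mesh) {
  nrow(mesh$elem_ijk) / prod(mesh$dim)
}

#' Element centroid coordinates (mm)
#' @param mesh A [voxel_mesh()].
#' @export
element_centroids <- function(mesh) {
  sweep(sweep(mesh$elem_ijk - 0.5, 2, mesh$h, "*"), 2, mesh$origin, "+")
}

#' Select node indices on a coordinate plane
#'
#' @param mesh A [voxel_mesh()].
#' @param axis 1, 2 or 3.
#' @param value Plane coordinate (mm).
#' @param grp Optional contact group filter.
#' @param tol Matching tolerance (default half a voxel).
#' @return Integer node indices (1-based).
#' @export
nodes_on_plane <- function(mesh, axis, value, grp = NULL, tol = NULL) {
  if (is.null(tol)) tol <- mesh$h[axis] / 2
  sel <- abs(mesh$node_xyz[, axis] - value) < tol
  if (!is.null(grp)) sel <- sel & mesh$node_grp %in% grp
  which(sel)
}

#' Select node indices inside an axis-aligned box
#'
#' @param mesh A [voxel_mesh()].
#' @param lo,hi Box corners (mm, length 3).
#' @param grp Optional contact group filter.
#' @return Integer node indices (1-based).
#' @export
nodes_in_box <- function(mesh, lo, hi, grp = NULL) {
  xyz <- mesh$node_xyz
  sel <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
    xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
    xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
  if (!is.null(grp)) sel <- sel & mesh$node_grp %in% grp
  which(sel)
}

#' Matched node pairs across a contact interface
#'
#' Finds grid positions whose nodes were duplicated between two contact
#' groups (i.e. coincident nodes on the interface plane) and returns the
#' index pairs, ordered consistently.
#'
#' @param mesh A [voxel_mesh()].
#' @param grpA,grpB The two contact groups.
#' @return Two-column integer matrix (`iA`, `iB`) of node indices.
#' @export
contact_node_pairs <- function(mesh, grpA, grpB) {
  inA <- which(mesh$node_grp == grpA)
  inB <- which(mesh$node_grp == grpB)
  m <- match(mesh$node_gid[inA], mesh$node_gid[inB])
  keep <- !is.na(m)
  cbind(iA = inA[keep], iB = inB[m[keep]])
}

#' Number of connected solid components
#'
#' Elements are connected when they share a face and belong to the same
#' contact group.  Meshes with more than one component cannot be solved
#' without interface springs; the FE driver uses this diagnostic.
#'
#' @param mesh A [voxel_mesh()].
#' @return Integer component count.
#' @export
mesh_n_components <- function(mesh) {
  dm <- mesh$dim
  vol <- array(0L, dm)
  vol[mesh$elem_lin] <- seq_len(nrow(mesh$elem_ijk))
  gvol <- array(0L, dm)
  gvol[mesh$elem_lin] <- mesh$grp_e
  pairs <- NULL
  for (ax in 1:3) {
    idx1 <- lapply(1:3, function(a) seq_len(dm[a] - (a == ax)))
    idx2 <- idx1
    idx2[[ax]] <- idx2[[ax]] + 1L
    a1 <- do.call(`[`, c(list(vol), idx1, list(drop = FALSE)))
    a2 <- do.call(`[`, c(list(vol), idx2, list(drop = FALSE)))
    g1 <- do.call(`[`, c(list(gvol), idx1, list(drop = FALSE)))
    g2 <- do.call(`[`, c(list(gvol), idx2, list(drop = FALSE)))
    ok <- a1 > 0 & a2 > 0 & g1 == g2
    pairs <- rbind(pairs, cbind(a1[ok], a2[ok]))
  }
  n <- nrow(mesh$elem_ijk)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
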