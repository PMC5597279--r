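#' Export a voxel mesh (with optional fields) as legacy ASCII VTK
#'
#' Unstructured hexahedral grid; per-element fields (e.g. von Mises) are
#' written as CELL_DATA scalars and per-node displacement as POINT_DATA
#' vectors.  Readable by ParaView/VTK.
#'
#' @param mesh A [voxel_mesh()].
#' @param path Output file.
#' @param cell_fields Named list of per-element numeric vectors.
#' @param displacement Optional displacement vector (length `ndof`, mm).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_fields = list(), displacement = NULL) {
  nel <- nrow(mesh$elem_ijk)
  nn <- mesh$nnodes
  con <- file(path, "w")
  on.exit(close(con))
  cat("# vtk DataFile Version 3.0\n", file = con)
  cat("stiffmatch voxel mesh (element-centroid values)\n", file = con)
  cat("ASCII\nDATASET UNSTRUCTURED_GRID\n", file = con)
  cat(sprintf("POINTS %d double\n", nn), file = con)
  write(t(mesh$node_xyz), file = con, ncolumns = 3)
  cat(sprintf("CELLS %d %d\n", nel, 9 * nel), file = con)
  # VTK_HEXAHEDRON ordering: bottom ring counter-clockwise then top ring
  perm <- c(1, 2, 4, 3, 5, 6, 8, 7)
  write(t(cbind(8L, mesh$conn[, perm, drop = FALSE] - 1L)), file = con,
        ncolumns = 9)
  cat(sprintf("CELL_TYPES %d\n", nel), file = con)
  write(rep(12L, nel), file = con, ncolumns = 20)
  if (length(cell_fields) > 0) {
    cat(sprintf("CELL_DATA %d\n", nel), file = con)
    for (nm in names(cell_fields)) {
      cat(sprintf("SCALARS %s double 1\nLOOKUP_TABLE default\n", nm),
          file = con)
      write(cell_fields[[nm]], file = con, ncolumns = 9)
    }
  }
  if (!is.null(displacement)) {
    cat(sprintf("POINT_DATA %d\nVECTORS displacement double\n", nn),
        file = con)
    write(matrix(displacement, nrow = 3), file = con, ncolumns = 3)
  }
  invisible(path)
}

#' Export the boundary surface of a voxel mesh as ASCII STL
#'
#' Exposed voxel faces (solid voxel with a void or out-of-grid neighbour)
#' are triangulated into two facets each.
#'
#' @param mesh A [voxel_mesh()].
#' @param path Output file.
#' @param name Solid name in the STL header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "stiffmatch") {
  dm <- mesh$dim
  h <- mesh$h
  vol <- array(FALSE, dm)
  vol[mesh$elem_lin] <- TRUE
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("solid %s\n", name), file = con)
  emit <- function(v1, v2, v3, nrm) {
    cat(sprintf("facet normal %g %g %g\n outer loop\n", nrm[1], nrm[2], nrm[3]),
        file = con)
    for (v in list(v1, v2, v3)) {
      cat(sprintf("  vertex %g %g %g\n", v[1], v[2], v[3]), file = con)
    }
    cat(" endloop\nendfacet\n", file = con)
  }
  ijk <- mesh$elem_ijk
  for (e in seq_len(nrow(ijk))) {
    i <- ijk[e, 1]; j <- ijk[e, 2]; k <- ijk[e, 3]
    x0 <- mesh$origin + (c(i, j, k) - 1) * h
    x1 <- x0 + h
    for (ax in 1:3) {
      for (side in c(-1L, 1L)) {
        nb <- c(i, j, k)
        nb[ax] <- nb[ax] + side
        exposed <- nb[ax] < 1 || nb[ax] > dm[ax] || !vol[nb[1], nb[2], nb[3]]
        if (!exposed) next
        nrm <- c(0, 0, 0); nrm[ax] <- side
        # face corners in the two axes != ax
        oth <- setdiff(1:3, ax)
        base <- x0
        base[ax] <- if (side == 1L) x1[ax] else x0[ax]
        p <- function(da, db) {
          v <- base
          v[oth[1]] <- if (da) x1[oth[1]] else x0[oth[1]]
          v[oth[2]] <- if (db) x1[oth[2]] else x0[oth[2]]
          v
        }
        emit(p(FALSE, FALSE), p(TRUE, FALSE), p(TRUE, TRUE), nrm)
        emit(p(FALSE, FALSE), p(TRUE, TRUE), p(FALSE, TRUE), nrm)
      }
    }
  }
  cat(sprintf("endsolid %s\n", name), file = con)
  invisible(path)
}

#' Write a porosity sweep or equivalent curve to CSV
#'
#' @param x A data frame (e.g. [porosity_modulus_sweep()] output) or an
#'   `equivalent_response`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  if (inherits(x, "equivalent_response")) {
    x <- data.frame(strain = x$strain, stress_MPa = x$stress,
                    vm_max_MPa = x$vm_max,
                    vm_max_filtered_MPa = x$vm_max_filtered)
  }
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON report (design reports, comparison tables, manifests)
#'
#' @param x A list or data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a flat JSON configuration file
#'
#' @param path JSON file with one block per material or one block of
#'   assembly parameters.
#' @return Named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
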