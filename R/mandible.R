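#' Configuration of the reduced mandibular-reconstruction assembly
#'
#' A parametric, prismatic stand-in for the CT-derived anatomy: two host
#' bone segments (cortical shell over cancellous core), a double-barrel
#' graft block filling a 40 mm resection, one inferior plate (78 x 4 x
#' 1.5 mm) and two superior plates (18 x 2.8 x 1 mm) on the buccal face,
#' screws as tie constraints, and compression-only contact planes at the
#' two host|graft cuts.
#'
#' Axes: x mesiodistal (length), y buccolingual (width), z superoinferior
#' (height).  Plates sit one voxel off the buccal face (`y = width`) and
#' connect to bone only through the screw ties.
#'
#' @param h Voxel edge lengths (mm, length 3).  The default (2 x 0.75 x
#'   2 mm, about 15k elements) resolves the inferior plate thickness with
#'   two voxels and solves each scenario in under a couple of minutes;
#'   `c(1, 0.5, 1)` is a finer setting for convergence checks.
#' @param host_length Length of each host segment (mm).
#' @param resection Resection/graft length (mm).
#' @param graft_width,graft_height Graft cross-section (mm).
#' @param cortical Cortical shell thickness of host and graft (mm).
#' @param barrel_height Height of the lower graft barrel (mm); the barrel
#'   junction carries its own cortical band.
#' @param plate_gap Bone-plate clearance in voxels (default 1).
#' @param bite_force Healthy-mandible bite resultant (N).
#' @param bite_fraction Fraction applied to reconstructed models.
#' @param pretension Pretension per plate (N).
#' @return An `assembly_config` list.
#' @export
assembly_config <- function(h = c(2, 0.75, 2),
                            host_length = 20, resection = 40,
                            graft_width = 14, graft_height = 38,
                            cortical = 3, barrel_height = 19,
                            plate_gap = 1,
                            bite_force = 526, bite_fraction = 0.60,
                            pretension = 100) {
  if (length(h) == 1) h <- rep(h, 3)
  Lx <- 2 * host_length + resection
  list(h = h, host_length = host_length, resection = resection,
       graft_width = graft_width, graft_height = graft_height,
       cortical = cortical, barrel_height = barrel_height,
       plate_gap = plate_gap,
       total_length = Lx,
       inf_plate = list(length = 78, width = 4, thickness = 1.5,
                        z0 = 2,
                        screw_x = c(6, 14, Lx / 2 - 6, Lx / 2 + 6,
                                    Lx - 14, Lx - 6)),
       sup_plate = list(length = 18, width = 2.8, thickness = 1,
                        z0 = graft_height - 2.8 - 2,
                        screw_off = 5),
       bite_patch = c(Lx / 2 - 5, Lx / 2 + 5),
       bite_force = bite_force, bite_fraction = bite_fraction,
       pretension = pretension)
}

#' Generate the reduced mandibular-reconstruction assembly
#'
#' Builds the voxel mesh with region and contact-group labels, the
#' contact node pairs at the two host|graft cuts, and the screw tie
#' springs.  Material tags: 1 host cortical, 2 host cancellous, 3 graft
#' cortical, 4 graft cancellous, 5 plates.
#'
#' @param config An [assembly_config()].
#' @param resected Build the resected/reconstructed model (default); with
#'   `FALSE` a contiguous healthy host bar (no graft, no plates) is
#'   produced.
#' @return A `reduced_assembly` object.
#' @export
generate_assembly <- function(config = assembly_config(), resected = TRUE) {
  h <- config$h
  # plates need at least 2 voxels through the thickness to bend
  if (resected && h[2] > config$inf_plate$thickness / 2) {
    stop("under-resolved plates: reduce h[2] to at most half the inferior plate thickness")
  }
  Lx <- config$total_length
  W <- config$graft_width
  Hh <- config$graft_height
  gapw <- config$plate_gap * h[2]
  tmax <- max(config$inf_plate$thickness, config$sup_plate$thickness)
  Ly <- W + gapw + tmax
  nx <- round(Lx / h[1]); ny <- ceiling(Ly / h[2]); nz <- round(Hh / h[3])
  cx <- (seq_len(nx) - 0.5) * h[1]
  cy <- (seq_len(ny) - 0.5) * h[2]
  cz <- (seq_len(nz) - 0.5) * h[3]
  X <- array(rep(cx, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(cy, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), dim = c(nx, ny, nz))

  tag <- array(0L, dim = c(nx, ny, nz))
  grp <- array(1L, dim = c(nx, ny, nz))
  xl <- config$host_length
  xr <- xl + config$resection
  bone_y <- Y < W
  host <- bone_y & (X < xl | X > xr)
  graft <- bone_y & X > xl & X < xr
  ct <- config$cortical
  shell_yz <- (Y < ct) | (Y > W - ct) | (Z < ct) | (Z > Hh - ct)
  if (!resected) {
    host <- bone_y
    graft <- graft & FALSE
  }
  tag[host & shell_yz] <- 1L
  tag[host & !shell_yz] <- 2L
  if (resected) {
    bb <- config$barrel_height
    barrel_band <- abs(Z - bb) < ct
    gshell <- shell_yz | barrel_band
    tag[graft & gshell] <- 3L
    tag[graft & !gshell] <- 4L
    grp[graft] <- 3L
    grp[host & X > xr] <- 2L
  }

  plates <- list()
  if (resected) {
    y0 <- W + gapw
    ip <- config$inf_plate
    x0 <- (Lx - ip$length) / 2
    inf_box <- X > x0 & X < x0 + ip$length &
      Y > y0 & Y < y0 + ip$thickness &
      Z > ip$z0 & Z < ip$z0 + ip$width
    tag[inf_box] <- 5L
    grp[inf_box] <- 4L
    plates$inferior <- list(box = c(x0, x0 + ip$length, y0,
                                    y0 + ip$thickness, ip$z0,
                                    ip$z0 + ip$width),
                            screw_x = ip$screw_x,
                            screw_z = rep(ip$z0 + ip$width / 2,
                                          length(ip$screw_x)),
                            mid_x = c(max(ip$screw_x[2], x0) + 1,
                                      min(ip$screw_x[5], x0 + ip$length) - 1),
                            area = ip$width * ip$thickness)
    sp <- config$sup_plate
    for (side in 1:2) {
      xc <- if (side == 1) xl else xr
      sx0 <- xc - sp$length / 2
      box <- X > sx0 & X < sx0 + sp$length &
        Y > y0 & Y < y0 + sp$thickness &
        Z > sp$z0 & Z < sp$z0 + sp$width
      tag[box] <- 5L
      grp[box] <- 4L
      plates[[if (side == 1) "sup_mesial" else "sup_distal"]] <- list(
        box = c(sx0, sx0 + sp$length, y0, y0 + sp$thickness,
                sp$z0, sp$z0 + sp$width),
        screw_x = c(xc - sp$screw_off, xc + sp$screw_off),
        screw_z = rep(sp$z0 + sp$width / 2, 2),
        mid_x = c(xc - sp$screw_off + 1, xc + sp$screw_off - 1),
        area = sp$width * sp$thickness)
    }
  }

  mesh <- voxel_mesh(tag, h = h, grp = grp)
  region_names <- c("host_cortical", "host_cancellous", "graft_cortical",
                    "graft_cancellous", "plate")
  region <- region_names[mesh$matid]
  # label which plate each plate element belongs to
  cen <- element_centroids(mesh)
  plate_of <- rep(NA_character_, nrow(cen))
  for (pn in names(plates)) {
    b <- plates[[pn]]$box
    sel <- mesh$matid == 5L & cen[, 1] > b[1] & cen[, 1] < b[2] &
      cen[, 3] > b[5] & cen[, 3] < b[6]
    plate_of[sel] <- pn
  }

  interfaces <- list()
  if (resected) {
    interfaces$mesial <- list(pairs = contact_node_pairs(mesh, 1L, 3L),
                              x = xl, normal = c(1, 0, 0))
    interfaces$distal <- list(pairs = contact_node_pairs(mesh, 3L, 2L),
                              x = xr, normal = c(1, 0, 0))
  }

  structure(list(config = config, mesh = mesh, region = region,
                 plate_of = plate_of, plates = plates,
                 interfaces = interfaces, resected = resected),
            class = "reduced_assembly")
}

#' @export
print.reduced_assembly <- function(x, ...) {
  cat(sprintf("Reduced mandible assembly (%s)\n",
              if (x$resected) "reconstructed" else "healthy"))
  print(x$mesh)
  if (x$resected) {
    cat(sprintf("  interfaces: %d + %d contact node pairs\n",
                nrow(x$interfaces$mesial$pairs),
                nrow(x$interfaces$distal$pairs)))
  }
  invisible(x)
}

# Screw tie springs: pair plate inner-face nodes near each screw axis with
# the nearest bone surface node.
screw_tie_springs <- function(assembly, k_tie) {
  mesh <- assembly$mesh
  cfg <- assembly$config
  W <- cfg$graft_width
  y_plate <- W + cfg$plate_gap * mesh$h[2]
  plate_nodes <- nodes_on_plane(mesh, 2, y_plate, grp = 4L)
  bone_nodes <- nodes_on_plane(mesh, 2, W, grp = c(1L, 2L, 3L))
  pxz <- mesh$node_xyz[plate_nodes, c(1, 3), drop = FALSE]
  bxz <- mesh$node_xyz[bone_nodes, c(1, 3), drop = FALSE]
  rsel <- max(1.4, sqrt(mesh$h[1]^2 + mesh$h[3]^2)) * 0.75
  pairs <- NULL
  for (pn in names(assembly$plates)) {
    pl <- assembly$plates[[pn]]
    for (s in seq_along(pl$screw_x)) {
      d2 <- (pxz[, 1] - pl$screw_x[s])^2 + (pxz[, 2] - pl$screw_z[s])^2
      near <- which(d2 < rsel^2)
      if (length(near) == 0) near <- which.min(d2)
      for (i in near) {
        j <- which.min((bxz[, 1] - pxz[i, 1])^2 + (bxz[, 2] - pxz[i, 2])^2)
        pairs <- rbind(pairs, c(plate_nodes[i], bone_nodes[j]))
      }
    }
  }
  make_springs(pairs, kn = k_tie, kt = k_tie, normal = c(0, 1, 0))
}

#' Loading scenario for the reduced assembly
#'
#' @param id `"A"` (bite only), `"B"` (pretension only), `"C"`
#'   (pretension + bite), or `"rest"` (neither).
#' @param pretension Pretension per plate (N); defaults to the assembly
#'   configuration value for scenarios B and C.
#' @param interface `"contact"` (compression-only, frictionless: the
#'   healing period) or `"bonded"` (healed junction).
#' @return A `load_scenario` list.
#' @export
load_scenario <- function(id = c("A", "B", "C", "rest"), pretension = NULL,
                          interface = c("contact", "bonded")) {
  id <- match.arg(id)
  interface <- match.arg(interface)
  list(id = id, pretension = pretension, interface = interface,
       bite = id %in% c("A", "C"),
       pretensioned = id %in% c("B", "C"))
}

#' Solve a loading scenario on the reduced assembly
#'
#' Condyle end faces are fixed; the bite resultant (60% of the healthy
#' 526 N by default) acts downward on the molar patch of the graft; plate
#' pretension is realized as an axial contraction eigenstrain in the plate
#' mid-spans, equilibrated together with the bite load.  The host|graft
#' cuts transmit compression only (frictionless) in `"contact"` mode.
#'
#' @param assembly A [generate_assembly()] result.
#' @param scenario A [load_scenario()].
#' @param plate One of `"Ti"` (dense Ti-6Al-4V, 112 GPa) or `"NiTi"`
#'   (stiffness-matched porous plate at its homogenized equivalent
#'   modulus).
#' @param plate_modulus Equivalent plate modulus (GPa) for the NiTi arm
#'   (default 12, the bone-matched target).
#' @param plate_amplification Local/equivalent stress amplification factor
#'   of the porous plate lattice (from [local_stress_report()]); the dense
#'   Ti arm uses 1.
#' @param cg_tol Linear solver tolerance.
#' @return List: `result` ([fe_solve_contact()] output), `summary` (per
#'   region mean/max von Mises, MPa), `interface_traction` (mean
#'   compressive normal traction, MPa), `plate_max_local` (amplified plate
#'   stress, MPa).
#' @export
apply_scenario <- function(assembly, scenario = load_scenario("C"),
                           plate = c("Ti", "NiTi"), plate_modulus = 12,
                           plate_amplification = NULL, cg_tol = 1e-7) {
  plate <- match.arg(plate)
  mesh <- assembly$mesh
  cfg <- assembly$config
  mats <- assembly_materials(plate, plate_modulus)
  if (is.null(plate_amplification)) plate_amplification <- 1

  Lx <- cfg$total_length
  ends <- c(nodes_on_plane(mesh, 1, 0), nodes_on_plane(mesh, 1, Lx))
  fix <- list(bc_fix(ends, 1:3, 0))

  force <- NULL
  if (scenario$bite) {
    patch <- nodes_in_box(mesh,
                          c(cfg$bite_patch[1], 0, cfg$graft_height - 1e-6),
                          c(cfg$bite_patch[2], cfg$graft_width,
                            cfg$graft_height + 1e-6),
                          grp = if (assembly$resected) 3L else 1L)
    force <- list(bc_force(patch, 3, -cfg$bite_force * cfg$bite_fraction))
  }

  eig <- NULL
  pret <- if (!is.null(scenario$pretension)) scenario$pretension else
    cfg$pretension
  if (scenario$pretensioned && pret > 0 && assembly$resected) {
    eig <- matrix(0, 6, nrow(mesh$elem_ijk))
    cen <- element_centroids(mesh)
    Ep <- mats[[5]]$E * 1e3
    for (pn in names(assembly$plates)) {
      pl <- assembly$plates[[pn]]
      sel <- which(!is.na(assembly$plate_of) & assembly$plate_of == pn &
                     cen[, 1] > pl$mid_x[1] & cen[, 1] < pl$mid_x[2])
      eig[1, sel] <- -pret / (Ep * pl$area)
    }
  }

  springs <- NULL
  contact_rows <- integer(0)
  if (assembly$resected) {
    E_stiff <- 26.8e3  # graft cortical, the stiffer contact neighbour
    kn <- 100 * E_stiff * mean(mesh$h)
    k_tie <- 100 * 112e3 * mean(mesh$h)
    bonded <- scenario$interface == "bonded"
    s1 <- make_springs(assembly$interfaces$mesial$pairs, kn,
                       if (bonded) kn else 0, c(1, 0, 0))
    s2 <- make_springs(assembly$interfaces$distal$pairs, kn,
                       if (bonded) kn else 0, c(1, 0, 0))
    st <- screw_tie_springs(assembly, k_tie)
    springs <- rbind(s1, s2, st)
    if (!bonded) contact_rows <- seq_len(nrow(s1) + nrow(s2))
  }

  res <- if (is.null(springs)) {
    fe_solve_linear(mesh, mats, fix, force, eigenstrain = eig,
                    cg_tol = cg_tol)
  } else {
    fe_solve_contact(mesh, mats, fix, force, springs, contact_rows,
                     eigenstrain = eig, cg_tol = cg_tol)
  }

  summary <- region_summary(assembly, res)
  itr <- interface_traction(assembly, res)
  pmax <- if (any(assembly$region == "plate"))
    filtered_max(res$vm[assembly$region == "plate"]) else NA_real_
  list(result = res, summary = summary,
       interface_traction = itr,
       plate_max_vm = pmax,
       plate_max_local = pmax * plate_amplification,
       plate = plate, scenario = scenario$id)
}

# Dense-material set of the reduced model (moduli GPa).
assembly_materials <- function(plate = "Ti", plate_modulus = 12) {
  list(material_linear(17, 0.3, name = "host cortical"),
       material_linear(0.96, 0.3, name = "host cancellous"),
       material_linear(26.8, 0.3, name = "graft cortical"),
       material_linear(1.65, 0.3, name = "graft cancellous"),
       if (plate == "Ti") material_linear(112, 0.3, 970, "Ti-6Al-4V")
       else material_linear(plate_modulus, 0.33, 1011, "porous NiTi (equivalent)"))
}

# Mean/max von Mises per region (MPa).
region_summary <- function(assembly, res) {
  regs <- sort(unique(assembly$region))
  do.call(rbind, lapply(regs, function(r) {
    v <- res$vm[assembly$region == r]
    data.frame(region = r, mean_vm = mean(v), max_vm = filtered_max(v),
               max_vm_raw = max(v))
  }))
}

# Mean compressive normal traction over the host|graft interfaces (MPa)
# and the largest transmitted tensile force (should be ~0 in contact mode).
interface_traction <- function(assembly, res) {
  if (!assembly$resected || is.null(res$spring_normal_force)) {
    return(list(mean_compressive = 0, max_tensile_force = 0))
  }
  n1 <- nrow(assembly$interfaces$mesial$pairs)
  n2 <- nrow(assembly$interfaces$distal$pairs)
  f <- res$spring_normal_force[seq_len(n1 + n2)]
  area <- 2 * assembly$config$graft_width * assembly$config$graft_height
  list(mean_compressive = sum(pmax(f, 0)) / area,
       max_tensile_force = max(-pmin(f, 0), 0))
}

#' Compare dense Ti against stiffness-matched NiTi plates
#'
#' Runs the requested scenarios for both plate arms on the same assembly
#' and load set and tabulates the NiTi/Ti ratios of the graft and host
#' average von Mises stress, the interface compressive traction, and the
#' maximum local plate stress (the NiTi arm's macroscopic plate stress is
#' amplified by the porous lattice factor).
#'
#' @param assembly A [generate_assembly()] result.
#' @param scenarios Character vector of scenario ids.
#' @param plate_modulus NiTi equivalent plate modulus (GPa).
#' @param niti_amplification Local stress amplification of the porous
#'   NiTi lattice; computed by the homogenization module
#'   ([local_stress_report()]).
#' @param ti_amplification Amplification of the Ti arm (1: dense plates).
#' @param ... Passed to [apply_scenario()].
#' @return List with `table` (per-scenario metrics and ratios) and the
#'   raw per-arm outputs.
#' @export
compare_models <- function(assembly, scenarios = c("A", "B", "C"),
                           plate_modulus = 12, niti_amplification,
                           ti_amplification = 1, ...) {
  runs <- list()
  rows <- lapply(scenarios, function(sc) {
    a_ti <- apply_scenario(assembly, load_scenario(sc), plate = "Ti",
                           plate_modulus = plate_modulus,
                           plate_amplification = ti_amplification, ...)
    a_ni <- apply_scenario(assembly, load_scenario(sc), plate = "NiTi",
                           plate_modulus = plate_modulus,
                           plate_amplification = niti_amplification, ...)
    runs[[sc]] <<- list(Ti = a_ti, NiTi = a_ni)
    g_ti <- a_ti$summary$mean_vm[a_ti$summary$region == "graft_cortical"]
    g_ni <- a_ni$summary$mean_vm[a_ni$summary$region == "graft_cortical"]
    h_ti <- a_ti$summary$mean_vm[a_ti$summary$region == "host_cortical"]
    h_ni <- a_ni$summary$mean_vm[a_ni$summary$region == "host_cortical"]
    data.frame(scenario = sc,
               graft_vm_Ti = g_ti, graft_vm_NiTi = g_ni,
               graft_ratio = g_ni / g_ti,
               host_vm_Ti = h_ti, host_vm_NiTi = h_ni,
               host_ratio = h_ni / h_ti,
               traction_Ti = a_ti$interface_traction$mean_compressive,
               traction_NiTi = a_ni$interface_traction$mean_compressive,
               plate_local_Ti = a_ti$plate_max_local,
               plate_local_NiTi = a_ni$plate_max_local,
               plate_ratio = a_ni$plate_max_local / a_ti$plate_max_local)
  })
  list(table = do.call(rbind, rows), runs = runs)
}

#' Interface traction versus pretension sweep
#'
#' @param assembly A [generate_assembly()] result.
#' @param pretensions Pretension levels (N).
#' @param plate Plate arm.
#' @param ... Passed to [apply_scenario()].
#' @return Data frame with `pretension` and `mean_compressive` (MPa).
#' @export
pretension_sweep <- function(assembly, pretensions = c(0, 50, 100),
                             plate = "NiTi", ...) {
  rows <- lapply(pretensions, function(p) {
    sc <- load_scenario("B", pretension = p)
    out <- apply_scenario(assembly, sc, plate = plate, ...)
    data.frame(pretension = p,
               mean_compressive = out$interface_traction$mean_compressive)
  })
  do.call(rbind, rows)
}
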