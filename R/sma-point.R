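#' Material point state for the superelastic model
#'
#' @param xi Martensite volume fraction in `[0, 1]`.
#' @param eps_t Transformation strain: scalar (1D) or length-6 Voigt vector
#'   with engineering shears (3D).
#' @param eps Current total strain (same shape as `eps_t`); carried so that
#'   strain-increment driving is stateless for the caller.
#' @return A `sma_state` object.
#' @export
sma_state <- function(xi = 0, eps_t = 0, eps = 0) {
  if (xi < -1e-12 || xi > 1 + 1e-12) stop("xi must lie in [0, 1]")
  xi <- min(max(xi, 0), 1)
  stopifnot(length(eps_t) %in% c(1L, 6L), length(eps) == length(eps_t))
  structure(list(xi = xi, eps_t = eps_t, eps = eps), class = "sma_state")
}

# Reuss mixture modulus (MPa) at martensite fraction xi.
sma_mixE <- function(params, xi) {
  1e3 / ((1 - xi) / params$E_A + xi / params$E_M)
}

#' Integrate the 1D superelastic model over a strain increment
#'
#' Explicit scalar return mapping on the martensite fraction: the uniaxial
#' stress must stay on the forward plateau line
#' `|sigma| = fwd_start + (fwd_finish - fwd_start) * xi` while transforming
#' forward, and on the reverse line while reverting.  Phase moduli are
#' mixed in series (Reuss) and the transformation strain is `H * xi`
#' (signed by the loading direction).
#'
#' @param params [sma_params()].
#' @param state [sma_state()] with scalar `eps_t` (a virgin state by
#'   default).
#' @param strain_increment Uniaxial strain increment (dimensionless).
#' @param strain_cap Maximum admissible |total strain| (default 6%).
#' @return List with `stress` (MPa) and the updated `state`.
#' @export
integrate_point_1d <- function(params, state = sma_state(),
                               strain_increment, strain_cap = 0.06) {
  stopifnot(inherits(params, "sma_params"), length(state$eps_t) == 1L)
  eps <- state$eps + strain_increment
  if (abs(eps) > strain_cap) {
    stop(sprintf("total strain %.4f exceeds the configured cap %.4f",
                 eps, strain_cap))
  }
  s <- transformation_stresses(params)
  sfs <- s[["fwd_start"]]; dsf <- s[["fwd_finish"]] - sfs
  srf <- s[["rev_finish"]]; dsr <- s[["rev_start"]] - srf
  xi_n <- state$xi; et_n <- state$eps_t
  sig_tr <- sma_mixE(params, xi_n) * (eps - et_n)
  tol <- 1e-8 * max(abs(sig_tr), sfs)

  stress_at <- function(x, et) sma_mixE(params, x) * (eps - et)

  # The plateau equations use the stress resolved along the transformation
  # direction (signed), not |stress|: the unsigned form has a spurious
  # second root where the transformation strain overshoots the total
  # strain and the stress changes sign.
  if (xi_n < 1 && abs(sig_tr) > sfs + dsf * xi_n + tol) {
    sgn <- sign(sig_tr)
    f <- function(x) {
      et <- et_n + params$H * (x - xi_n) * sgn
      sgn * stress_at(x, et) - (sfs + dsf * x)
    }
    if (f(1) >= 0) {
      xi <- 1
    } else {
      xi <- uniroot(f, c(xi_n, 1), tol = 1e-12)$root
    }
    et <- et_n + params$H * (xi - xi_n) * sgn
  } else if (xi_n > 0 && abs(sig_tr) < srf + dsr * xi_n - tol) {
    sgn <- if (et_n != 0) sign(et_n) else sign(sig_tr)
    f <- function(x) {
      et <- et_n * (x / xi_n)
      sgn * stress_at(x, et) - (srf + dsr * x)
    }
    if (f(0) <= 0) {
      xi <- 0
    } else {
      xi <- uniroot(f, c(0, xi_n), tol = 1e-12)$root
    }
    et <- et_n * (xi / xi_n)
  } else {
    xi <- xi_n; et <- et_n
  }
  list(stress = stress_at(xi, et),
       state = sma_state(xi = xi, eps_t = et, eps = eps))
}

#' Integrate the 3D superelastic model over a strain tensor increment
#'
#' Small-strain, von Mises-driven generalization of the 1D phase-diagram
#' model (radial return mapping, numerically consistent tangent).  Reduces
#' to [integrate_point_1d()] under uniaxial stress states.
#'
#' @param params [sma_params()].
#' @param state [sma_state()] with length-6 `eps_t` (Voigt, engineering
#'   shears).
#' @param strain_increment Length-6 Voigt strain increment.
#' @return List with `stress` (length-6, MPa), `tangent` (6x6 algorithmic
#'   tangent, MPa), and the updated `state`.
#' @export
integrate_point_3d <- function(params, state = sma_state(eps_t = numeric(6),
                                                         eps = numeric(6)),
                               strain_increment) {
  stopifnot(inherits(params, "sma_params"), length(strain_increment) == 6L,
            length(state$eps_t) == 6L)
  eps <- state$eps + strain_increment
  out <- sma_point_cpp(eps, state$xi, state$eps_t, sma_pars_vec(params))
  list(stress = out$sigma, tangent = out$D,
       state = sma_state(xi = out$xi, eps_t = out$eps_t, eps = eps))
}

#' Uniaxial loading curve (loading branch only)
#'
#' @param params [sma_params()].
#' @param max_strain Final strain.
#' @param n Number of points.
#' @return Data frame with `strain`, `stress` (MPa), `xi`.
#' @export
sma_curve_1d <- function(params, max_strain, n = 60) {
  sma_loop_1d(params, seq(0, max_strain, length.out = n))
}

#' Integrate the 1D model along a strain path
#'
#' @param params [sma_params()].
#' @param strain_path Numeric vector of total strain values (the path is
#'   traversed in order, starting from a virgin state).
#' @param state Initial [sma_state()].
#' @return Data frame with `strain`, `stress` (MPa), `xi`; the final state
#'   is attached as attribute `"state"`.
#' @export
sma_loop_1d <- function(params, strain_path, state = sma_state()) {
  stress <- xi <- numeric(length(strain_path))
  for (i in seq_along(strain_path)) {
    r <- integrate_point_1d(params, state, strain_path[i] - state$eps)
    state <- r$state
    stress[i] <- r$stress
    xi[i] <- state$xi
  }
  structure(data.frame(strain = strain_path, stress = stress, xi = xi),
            state = state)
}

#' Hysteresis loop dissipation
#'
#' Net specific work over a strain path, `integral sigma d eps` by the
#' trapezoid rule (MPa = mJ/mm^3).  Positive for a closed superelastic
#' loop (dissipated energy), zero for a purely elastic excursion.
#'
#' @param strain,stress Numeric vectors tracing the path in order.
#' @export
loop_dissipation <- function(strain, stress) {
  n <- length(strain)
  sum((stress[-1] + stress[-n]) / 2 * diff(strain))
}

#' Drive the 3D point model under uniaxial stress
#'
#' Mixed control: the axial strain follows the given targets while the
#' lateral normal stresses are iterated to zero (transverse isotropy makes
#' the two lateral strains equal).  This is the consistency oracle linking
#' the 3D return mapping to the 1D model.
#'
#' @param params [sma_params()].
#' @param strain_targets Axial strain path.
#' @param axis Loading axis (1, 2 or 3).
#' @param tol Lateral stress tolerance relative to the axial stress.
#' @return Data frame with `strain`, `stress` (axial, MPa), `xi`,
#'   `lateral_stress` (max |off-axis| component, MPa).
#' @export
drive_uniaxial_3d <- function(params, strain_targets, axis = 1, tol = 1e-8) {
  pv <- sma_pars_vec(params)
  lat <- setdiff(1:3, axis)
  state <- sma_state(eps_t = numeric(6), eps = numeric(6))
  el <- 0
  out <- data.frame(strain = strain_targets, stress = NA_real_, xi = NA_real_,
                    lateral_stress = NA_real_)
  for (i in seq_along(strain_targets)) {
    ea <- strain_targets[i]
    for (it in 1:60) {
      eps <- numeric(6)
      eps[axis] <- ea
      eps[lat] <- el
      r <- sma_point_cpp(eps, state$xi, state$eps_t, pv)
      flat <- mean(r$sigma[lat])
      scale <- max(abs(r$sigma[axis]), 1)
      if (abs(flat) < tol * scale) break
      dfl <- sum(r$D[lat[1], lat]) # d sigma_lat / d e_lat (both components)
      el <- el - flat / dfl
    }
    state <- sma_state(xi = r$xi, eps_t = r$eps_t, eps = eps)
    out$stress[i] <- r$sigma[axis]
    out$xi[i] <- r$xi
    out$lateral_stress[i] <- max(abs(r$sigma[-axis]))
  }
  structure(out, state = state)
}
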