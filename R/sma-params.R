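#' Superelastic NiTi material parameters
#'
#' Bundles the constants of the phase-diagram superelastic model: phase
#' moduli, transformation temperatures, stress-temperature slopes, the
#' maximum uniaxial transformation strain, and the yield strength.  The
#' default values are those measured on SLM-fabricated Ni-rich NiTi at
#' body temperature: austenite modulus 37 GPa, martensite modulus 42 GPa,
#' Poisson ratio 0.33, transformation temperatures Mf = 243 K < Ms = 263 K
#' < As = 270 K < Af = 280 K, and yield strength 1011 MPa.  The
#' stress-temperature slopes `C_M`, `C_A` and the transformation strain
#' `H` are configured defaults typical of Ni-rich NiTi in compression,
#' not measured values; [calibrate_sma()] fits them to a stress-strain
#' table when one is available.
#'
#' @param E_A Austenite Young's modulus (GPa).
#' @param E_M Martensite Young's modulus (GPa).
#' @param nu Poisson ratio.
#' @param Ms,Mf,As,Af Transformation temperatures (K); must satisfy
#'   `Mf < Ms < As < Af`.
#' @param C_M,C_A Stress-temperature slopes of the martensite and austenite
#'   transformation lines (MPa/K).
#' @param H Maximum uniaxial transformation strain (dimensionless).
#' @param sigma_y Yield strength (MPa).
#' @param T_op Operating temperature (K); superelasticity requires
#'   `T_op > Af`.
#' @return An object of class `sma_params`.
#' @examples
#' p <- sma_params()
#' transformation_stresses(p)
#' @export
sma_params <- function(E_A = 37, E_M = 42, nu = 0.33,
                       Ms = 263, Mf = 243, As = 270, Af = 280,
                       C_M = 7, C_A = 7, H = 0.04,
                       sigma_y = 1011, T_op = 310) {
  stopifnot(E_A > 0, E_M > 0, C_M > 0, C_A > 0, H > 0, sigma_y > 0)
  if (!(nu > 0 && nu < 0.5)) stop("nu must lie in (0, 0.5)")
  if (!(Mf < Ms && Ms < As && As < Af)) {
    stop("transformation temperatures must satisfy Mf < Ms < As < Af")
  }
  structure(list(E_A = E_A, E_M = E_M, nu = nu,
                 Ms = Ms, Mf = Mf, As = As, Af = Af,
                 C_M = C_M, C_A = C_A, H = H,
                 sigma_y = sigma_y, T_op = T_op),
            class = "sma_params")
}

#' @export
print.sma_params <- function(x, ...) {
  cat("Superelastic NiTi parameters\n")
  cat(sprintf("  E_A = %g GPa, E_M = %g GPa, nu = %g\n", x$E_A, x$E_M, x$nu))
  cat(sprintf("  Mf/Ms/As/Af = %g/%g/%g/%g K, T_op = %g K\n",
              x$Mf, x$Ms, x$As, x$Af, x$T_op))
  cat(sprintf("  C_M = %g, C_A = %g MPa/K, H = %g, sigma_y = %g MPa\n",
              x$C_M, x$C_A, x$H, x$sigma_y))
  invisible(x)
}

#' Critical uniaxial transformation stresses
#'
#' Clausius-Clapeyron construction: the four transformation stresses at the
#' operating temperature follow from linear transformation lines in
#' stress-temperature space, e.g. forward start = `C_M * (T_op - Ms)`.
#' All four are positive only above Af (the superelastic regime).
#'
#' @param params An [sma_params()] object.
#' @return Named numeric vector (MPa): `fwd_start`, `fwd_finish`,
#'   `rev_start`, `rev_finish`.
#' @export
transformation_stresses <- function(params) {
  stopifnot(inherits(params, "sma_params"))
  if (params$T_op <= params$Af) {
    stop("superelastic loop undefined: T_op must exceed Af (",
         params$Af, " K)")
  }
  c(fwd_start  = params$C_M * (params$T_op - params$Ms),
    fwd_finish = params$C_M * (params$T_op - params$Mf),
    rev_start  = params$C_A * (params$T_op - params$As),
    rev_finish = params$C_A * (params$T_op - params$Af))
}

# Internal: parameter vector for the C++ point model (moduli in MPa).
sma_pars_vec <- function(params) {
  s <- transformation_stresses(params)
  c(params$E_A * 1e3, params$E_M * 1e3, params$nu, params$H,
    s[["fwd_start"]], s[["fwd_finish"]], s[["rev_start"]], s[["rev_finish"]])
}

#' Calibrate transformation constants from a uniaxial stress-strain table
#'
#' Least-squares fit of the plateau constants to a measured superelastic
#' loading curve: the forward plateau start stress and the plateau slope
#' identify `C_M` (given the transformation temperatures and operating
#' temperature) and `H`.  Only the loading branch is used; `C_A` is kept
#' proportional to the fitted `C_M`.
#'
#' @param params Starting [sma_params()] set (temperatures and moduli are
#'   kept fixed).
#' @param strain,stress Numeric vectors: measured uniaxial loading curve
#'   (strain dimensionless, stress MPa, monotone loading).
#' @return An updated `sma_params` object with fitted `C_M`, `C_A`, `H`.
#' @export
calibrate_sma <- function(params, strain, stress) {
  stopifnot(length(strain) == length(stress), length(strain) >= 5)
  obj <- function(x) {
    p <- params
    p$C_M <- x[1]; p$C_A <- x[1] * params$C_A / params$C_M; p$H <- x[2]
    sim <- sma_curve_1d(p, max(strain), n = length(strain))
    sum((approx(sim$strain, sim$stress, xout = strain, rule = 2)$y - stress)^2)
  }
  fit <- stats::optim(c(params$C_M, params$H), obj,
                      lower = c(0.5, 0.005), upper = c(30, 0.08),
                      method = "L-BFGS-B")
  params$C_M <- fit$par[1]
  params$C_A <- fit$par[1] * params$C_A / params$C_M
  params$H <- fit$par[2]
  params
}

#' Linear elastic material definition
#'
#' @param E Young's modulus (GPa).
#' @param nu Poisson ratio.
#' @param sigma_y Optional yield strength (MPa); for Ti-6Al-4V the band
#'   970-1030 MPa applies and the lower bound is used for safety flags.
#' @param name Material label.
#' @return Object of class `linear_material` holding the 6x6 isotropic
#'   stiffness matrix in Voigt notation (MPa, engineering shears).
#' @export
material_linear <- function(E, nu, sigma_y = NA_real_, name = "material") {
  stopifnot(E > 0, nu > 0, nu < 0.5)
  Emp <- E * 1e3
  lam <- Emp * nu / ((1 + nu) * (1 - 2 * nu))
  G <- Emp / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * G
  diag(D)[4:6] <- G
  structure(list(E = E, nu = nu, sigma_y = sigma_y, name = name, D = D),
            class = "linear_material")
}

#' Bundled material property tables
#'
#' Reads the material parameter fixtures shipped with the package:
#' the linear mandible-model constituents (cortical and cancellous bone,
#' fibular graft, teeth, periodontal ligament, Ti-6Al-4V), the compression
#' test moduli and yield strengths, and the superelastic NiTi parameter
#' set.
#'
#' @param which One of `"mandible"`, `"compression"`, `"niti"`.
#' @return A data frame (`"mandible"`, `"compression"`) or an
#'   [sma_params()] object (`"niti"`).
#' @export
load_material_table <- function(which = c("mandible", "compression", "niti")) {
  which <- match.arg(which)
  path <- system.file("extdata", "materials.json", package = "stiffmatch")
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (which == "niti") {
    do.call(sma_params, as.list(tab$niti_superelastic))
  } else if (which == "compression") {
    tab$compression_test
  } else {
    tab$mandible_components
  }
}
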