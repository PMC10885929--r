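#' Physical parameters of the blood conductivity and rheology models
#'
#' Bundles the constants used throughout the package, in strict SI units:
#' the red-blood-cell (RBC) geometry, plasma conductivity, hematocrit, and
#' the rheology constants. Defaults are the standard literature values for
#' healthy human blood.
#'
#' RBCs are idealised as oblate spheroids with short semiaxis `a` and two
#' equal long semiaxes `b`, so the undeformed aspect ratio is
#' `lambda = a/b < 1`.
#'
#' The dynamic blood viscosity deserves a note. The Merrill hematocrit
#' relation ([blood_viscosity()]) applied to the tabulated plasma viscosity
#' `eta_pl = 4.8e-2` kg/(m s) yields a blood viscosity inconsistent with the
#' kinematic viscosity `nu_bl = 4.59e-5` m^2/s that the benchmark flow cases
#' (and the conductivity-ratio results) are based on. `blood_params()`
#' therefore carries an explicit `eta_bl_override`, defaulting to
#' `rho_bl * 4.59e-5 = 0.048654` kg/(m s), and every computation in the
#' package uses [eta_bl()] which prefers the override. Set
#' `eta_bl_override = NULL` to fall back to the Merrill value.
#'
#' @param lambda Undeformed RBC aspect ratio a/b (dimensionless, in (0,1)).
#' @param sigma_pl Plasma electrical conductivity (S/m).
#' @param hematocrit RBC volume fraction H (dimensionless, in `[0,1)`).
#' @param a Short RBC semiaxis (m).
#' @param b Long RBC semiaxis (m).
#' @param mu RBC membrane shear modulus (kg/s^2).
#' @param k Orientation/disorientation constant of the alignment-fraction
#'   law (s^-1/2).
#' @param eta_pl Plasma dynamic viscosity (kg m^-1 s^-1). Retained for the
#'   Merrill relation; see Details.
#' @param rho_bl Blood density (kg/m^3).
#' @param eta_bl_override Dynamic blood viscosity (kg m^-1 s^-1) used in all
#'   stress/shear conversions, or `NULL` to derive it from `eta_pl` and
#'   `hematocrit` via [blood_viscosity()].
#'
#' @return An object of class `blood_params`: a named list of the above.
#' @examples
#' p <- blood_params()
#' eta_bl(p)
#' kinematic_viscosity(eta_bl(p), p$rho_bl)
#' @export
blood_params <- function(lambda = 0.38,
                         sigma_pl = 1.3,
                         hematocrit = 0.45,
                         a = 1.52e-6,
                         b = 4e-6,
                         mu = 1e-5,
                         k = 1,
                         eta_pl = 4.8e-2,
                         rho_bl = 1060,
                         eta_bl_override = 1060 * 4.59e-5) {
  p <- list(
    lambda = lambda, sigma_pl = sigma_pl, hematocrit = hematocrit,
    a = a, b = b, mu = mu, k = k, eta_pl = eta_pl, rho_bl = rho_bl,
    eta_bl_override = eta_bl_override
  )
  validate_blood_params(p)
  structure(p, class = "blood_params")
}

validate_blood_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("lambda", "sigma_pl", "hematocrit", "a", "b", "mu", "k",
              "eta_pl", "rho_bl")) {
    if (!num1(p[[f]])) stop("blood_params: `", f, "` must be a finite numeric scalar.", call. = FALSE)
  }
  if (!(p$lambda > 0 && p$lambda < 1)) {
    stop("blood_params: `lambda` = a/b must lie in (0, 1); RBCs are modelled as oblate spheroids.", call. = FALSE)
  }
  if (p$hematocrit < 0 || p$hematocrit >= 1) {
    stop("blood_params: `hematocrit` must lie in [0, 1).", call. = FALSE)
  }
  for (f in c("sigma_pl", "a", "b", "mu", "k", "eta_pl", "rho_bl")) {
    if (p[[f]] <= 0) stop("blood_params: `", f, "` must be strictly positive.", call. = FALSE)
  }
  if (abs(p$a / p$b - p$lambda) > 0.05 * p$lambda) {
    warning("blood_params: lambda and a/b disagree by more than 5%; lambda governs the shape factors.", call. = FALSE)
  }
  if (!is.null(p$eta_bl_override)) {
    if (!num1(p$eta_bl_override) || p$eta_bl_override <= 0) {
      stop("blood_params: `eta_bl_override` must be a positive scalar or NULL.", call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.blood_params <- function(x, ...) {
  cat("<blood_params>\n")
  rows <- blood_params_table(x)
  w <- max(nchar(rows$key))
  for (i in seq_len(nrow(rows))) {
    cat(sprintf("  %-*s  %-12s %s\n", w, rows$key[i],
                formatC(rows$value[i], digits = 6, width = 12),
                rows$unit[i]))
  }
  invisible(x)
}

# Tabular view used by print() and the CLI `params` report.
blood_params_table <- function(p) {
  tibble::tibble(
    key = c("lambda", "sigma_pl", "hematocrit", "a", "b", "mu", "k",
            "eta_pl", "rho_bl", "eta_bl (effective)"),
    value = c(p$lambda, p$sigma_pl, p$hematocrit, p$a, p$b, p$mu, p$k,
              p$eta_pl, p$rho_bl, eta_bl(p)),
    unit = c("-", "S/m", "-", "m", "m", "kg/s^2", "s^-1/2",
             "kg/(m s)", "kg/m^3", "kg/(m s)"),
    description = c(
      "RBC aspect ratio a/b (oblate)",
      "plasma conductivity",
      "RBC volume fraction",
      "short RBC semiaxis",
      "long RBC semiaxis",
      "membrane shear modulus",
      "orientation constant of the alignment law",
      "plasma dynamic viscosity (Merrill input; see ?blood_params)",
      "blood density",
      "dynamic blood viscosity used in stress/shear conversions"
    )
  )
}

#' Effective dynamic viscosity of blood
#'
#' Returns the dynamic blood viscosity used everywhere stresses and shear
#' rates are interconverted: the explicit override stored in the parameter
#' set when present, otherwise the Merrill hematocrit relation applied to
#' the plasma viscosity.
#'
#' @param params A [blood_params()] object.
#' @return Dynamic viscosity of blood (kg m^-1 s^-1).
#' @export
eta_bl <- function(params) {
  stopifnot(inherits(params, "blood_params"))
  if (!is.null(params$eta_bl_override)) {
    params$eta_bl_override
  } else {
    blood_viscosity(params$eta_pl, params$hematocrit)
  }
}

#' Merrill relation for whole-blood viscosity
#'
#' `eta_bl = eta_pl * (1 + 2.5 H + 7.32 H^2)`: dynamic viscosity of blood
#' as a function of plasma viscosity and hematocrit.
#'
#' @param eta_pl Plasma dynamic viscosity (kg m^-1 s^-1).
#' @param hematocrit RBC volume fraction in `[0, 1)`.
#' @return Dynamic viscosity of blood (kg m^-1 s^-1). Vectorised.
#' @examples
#' blood_viscosity(4.8e-2, 0.45) / 4.8e-2 # 3.6073
#' @export
blood_viscosity <- function(eta_pl, hematocrit) {
  stopifnot(all(eta_pl > 0))
  if (any(hematocrit < 0 | hematocrit >= 1)) {
    stop("`hematocrit` must lie in [0, 1).", call. = FALSE)
  }
  eta_pl * (1 + 2.5 * hematocrit + 7.32 * hematocrit^2)
}

#' Kinematic viscosity
#'
#' @param eta Dynamic viscosity (kg m^-1 s^-1).
#' @param rho Density (kg/m^3), strictly positive.
#' @return Kinematic viscosity (m^2/s). Vectorised.
#' @export
kinematic_viscosity <- function(eta, rho) {
  if (any(rho <= 0)) stop("`rho` must be strictly positive.", call. = FALSE)
  eta / rho
}

#' Pipe-flow Reynolds number
#'
#' `Re = u_mean * D / nu`, with the mean (bulk) velocity, vessel diameter
#' and kinematic viscosity.
#'
#' @param u_mean Mean velocity (m/s).
#' @param diameter Vessel diameter (m).
#' @param nu Kinematic viscosity (m^2/s).
#' @return Reynolds number (dimensionless). Vectorised.
#' @examples
#' reynolds_number(0.008, 0.04, 4.59e-5) # about 6.97
#' @export
reynolds_number <- function(u_mean, diameter, nu) {
  if (any(nu <= 0)) stop("`nu` must be strictly positive.", call. = FALSE)
  if (any(u_mean < 0) || any(diameter < 0)) {
    stop("`u_mean` and `diameter` must be non-negative.", call. = FALSE)
  }
  u_mean * diameter / nu
}
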