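#' Polar shape angle of an oblate spheroid
#'
#' `phi = arccos(lambda)` with `lambda = a/b` the ratio of the short to the
#' long semiaxis. The sphere (`lambda = 1`) gives 0, the flat disc
#' (`lambda = 0`) gives pi/2.
#'
#' @param lambda Aspect ratio in `[0, 1]`. Vectorised.
#' @return Shape angle in radians, in `[0, pi/2]`.
#' @export
shape_angle <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0 | lambda > 1)) {
    stop("`lambda` must lie in [0, 1]: the RBC is modelled as an oblate spheroid with lambda = a/b <= 1.",
         call. = FALSE)
  }
  acos(lambda)
}

#' Maxwell-Fricke shape factor M(lambda)
#'
#' `M = (phi - sin(phi) cos(phi)) * cos(phi) / sin(phi)^3` with
#' `phi = arccos(lambda)`. M increases from 0 (flat disc) to its sphere
#' limit 2/3; the removable 0/0 singularity at `lambda = 1` is evaluated by
#' its series limit.
#'
#' @param lambda Aspect ratio in `[0, 1]`. Vectorised.
#' @return Shape factor in `(0, 2/3]` (0 exactly at `lambda = 0`).
#' @export
shape_factor <- function(lambda) {
  phi <- shape_angle(lambda)
  out <- numeric(length(lambda))
  # series limit at the sphere: phi - sin(phi)cos(phi) ~ (2/3) phi^3
  sphere <- lambda > 1 - 1e-6
  out[sphere] <- 2 / 3
  s <- sin(phi[!sphere])
  c <- cos(phi[!sphere])
  out[!sphere] <- (phi[!sphere] - s * c) * c / s^3
  out
}

#' Orientation factors of a fully aligned suspension
#'
#' The Maxwell-Fricke orientation factors for spheroids aligned with their
#' short axis (`C_a = 1/M`) or a long axis (`C_b = 2/(2 - M)`) along the
#' field. At the sphere limit `M = 2/3` both equal 3/2.
#'
#' @param M Shape factor in `(0, 2/3]`. Vectorised.
#' @return A tibble with columns `C_a`, `C_b`.
#' @export
orientation_factors <- function(M) {
  if (any(!is.finite(M)) || any(M <= 0) || any(M > 2 / 3 + 1e-12)) {
    stop("`M` must lie in (0, 2/3].", call. = FALSE)
  }
  tibble::tibble(C_a = 1 / M, C_b = 2 / (2 - M))
}

#' Orientation factor of a randomly oriented suspension
#'
#' `C_r = (C_a + 2 C_b)/3`: the orientation average over the three spheroid
#' axes, used for the fraction of RBCs in unsteady (tumbling) motion.
#'
#' @param C_a,C_b Aligned orientation factors (each >= 1). Vectorised.
#' @return `C_r`, lying between `C_b` and `C_a`.
#' @export
random_orientation_factor <- function(C_a, C_b) {
  if (any(C_a < 1) || any(C_b < 1)) {
    stop("orientation factors must be >= 1.", call. = FALSE)
  }
  (C_a + 2 * C_b) / 3
}

#' Shear-deformed RBC aspect ratio
#'
#' Under the maximum shear stress `tau_max` a tank-treading RBC elongates;
#' its aspect ratio drops from the stationary `lambda` as
#' `lambda_d = lambda * (1 + tau_max * b / (4 mu))^-3`, with long semiaxis
#' `b` and membrane shear modulus `mu`.
#'
#' @param params A [blood_params()] object (supplies `lambda`, `b`, `mu`).
#' @param tau_max Maximum shear stress (Pa, >= 0). Vectorised.
#' @return Deformed aspect ratio in `(0, lambda]`.
#' @export
deformed_aspect_ratio <- function(params, tau_max) {
  stopifnot(inherits(params, "blood_params"))
  if (any(!is.finite(tau_max)) || any(tau_max < 0)) {
    stop("`tau_max` must be non-negative.", call. = FALSE)
  }
  params$lambda * (1 + tau_max * params$b / (4 * params$mu))^-3
}

#' Fraction of aligned (tank-treading) RBCs
#'
#' `f = gdot / (gdot + k * sqrt(gdot))`: rises from 0 at vanishing shear
#' rate to 1 asymptotically, interpolating between randomly oriented and
#' fully aligned cell populations.
#'
#' @param gamma_dot_max Maximum shear rate (s^-1, >= 0). Vectorised.
#' @param k Orientation constant (s^-1/2, > 0).
#' @return Aligned fraction in `[0, 1)`.
#' @export
aligned_fraction <- function(gamma_dot_max, k = 1) {
  if (any(!is.finite(gamma_dot_max)) || any(gamma_dot_max < 0)) {
    stop("`gamma_dot_max` must be non-negative.", call. = FALSE)
  }
  if (any(k <= 0)) stop("`k` must be strictly positive.", call. = FALSE)
  s <- sqrt(gamma_dot_max)
  # f = s / (s + k), exact also at gdot = 0
  s / (s + k)
}

#' Shear rate at a given aligned fraction
#'
#' Closed-form inverse of [aligned_fraction()]:
#' `gdot = (f k / (1 - f))^2`. With the default `k = 1` the conventional
#' low/high alignment boundaries f = 0.20 and f = 0.80 map to shear rates
#' 0.0625 and 16 s^-1.
#'
#' @param f Aligned fraction in `[0, 1)`. Vectorised.
#' @param k Orientation constant (s^-1/2, > 0).
#' @return Maximum shear rate (s^-1).
#' @export
alignment_shear_rate <- function(f, k = 1) {
  if (any(f < 0 | f >= 1)) stop("`f` must lie in [0, 1).", call. = FALSE)
  if (any(k <= 0)) stop("`k` must be strictly positive.", call. = FALSE)
  (f * k / (1 - f))^2
}

#' Classify a shear rate as low, intermediate or high with respect to alignment
#'
#' The boundaries are defined through the aligned fraction, not through
#' fixed shear rates: "low" means `f < 0.20`, "high" means `f > 0.80`.
#' With `k = 1` the boundaries are 0.0625 and 16 s^-1; for other `k` they
#' move with the alignment law.
#'
#' @param gamma_dot_max Maximum shear rate (s^-1, >= 0). Vectorised.
#' @param k Orientation constant (s^-1/2).
#' @param low,high Aligned-fraction boundaries.
#' @return A factor with levels `low`, `intermediate`, `high`.
#' @export
classify_shear_rate <- function(gamma_dot_max, k = 1, low = 0.20, high = 0.80) {
  f <- aligned_fraction(gamma_dot_max, k)
  cut(f, breaks = c(-Inf, low, high, Inf),
      labels = c("low", "intermediate", "high"), right = FALSE)
}

#' Interpolated orientation factors
#'
#' Mixes the fully aligned factors with the random-orientation factor by
#' the aligned fraction: `C_alpha = f C_a + (1 - f) C_r` and
#' `C_beta = f C_b + (1 - f) C_r`.
#'
#' @param C_a,C_b Aligned orientation factors.
#' @param C_r Random orientation factor.
#' @param f Aligned fraction in `[0, 1]`.
#' @return A tibble with columns `C_alpha`, `C_beta`. Vectorised.
#' @export
interpolate_orientation_factors <- function(C_a, C_b, C_r, f) {
  if (any(f < 0 | f > 1)) stop("`f` must lie in [0, 1].", call. = FALSE)
  tibble::tibble(
    C_alpha = f * C_a + (1 - f) * C_r,
    C_beta  = f * C_b + (1 - f) * C_r
  )
}

#' Maxwell-Fricke suspension conductivity for one orientation factor
#'
#' `sigma = sigma_pl * (1 - H) / (1 + (C - 1) H)`: conductivity of a
#' suspension of non-conducting spheroids at volume fraction `H` in plasma
#' of conductivity `sigma_pl`, for orientation factor `C`.
#'
#' @param C Orientation factor (>= 1). Vectorised.
#' @param params A [blood_params()] object (supplies `sigma_pl` and `H`).
#' @return Conductivity (S/m), in `(0, sigma_pl]`.
#' @export
conductivity_from_factor <- function(C, params) {
  stopifnot(inherits(params, "blood_params"))
  if (any(C < 1)) stop("orientation factor `C` must be >= 1.", call. = FALSE)
  H <- params$hematocrit
  params$sigma_pl * (1 - H) / (1 + (C - 1) * H)
}

#' Maxwell's conductivity of a suspension of spheres
#'
#' The sphere limit `sigma/sigma_pl = (1 - H)/(1 + H/2)`, used as an
#' independent check of the shape-factor chain at `lambda -> 1`.
#'
#' @param params A [blood_params()] object.
#' @return Conductivity (S/m).
#' @export
maxwell_sphere_conductivity <- function(params) {
  stopifnot(inherits(params, "blood_params"))
  H <- params$hematocrit
  params$sigma_pl * (1 - H) / (1 + H / 2)
}

#' Pointwise shear state (maximum shear stress and rate)
#'
#' A tibble of consistent `(tau_max, gamma_dot_max)` pairs. The two are
#' redundant through the Newtonian law `gamma_dot_max = tau_max / (2 eta_bl)`;
#' supply either one and the other is derived. Supplying both is allowed
#' only when they agree to 1e-6 relative, so an inconsistent pair can never
#' silently corrupt the alignment interpolation.
#'
#' @param params A [blood_params()] object (supplies `eta_bl`).
#' @param tau_max Maximum shear stress (Pa, >= 0), or `NULL`.
#' @param gamma_dot_max Maximum shear rate (s^-1, >= 0), or `NULL`.
#' @return A tibble with columns `tau_max`, `gamma_dot_max`.
#' @examples
#' shear_state(blood_params(), gamma_dot_max = 1.9)
#' @export
shear_state <- function(params, tau_max = NULL, gamma_dot_max = NULL) {
  stopifnot(inherits(params, "blood_params"))
  eta <- eta_bl(params)
  if (is.null(tau_max) && is.null(gamma_dot_max)) {
    stop("supply `tau_max`, `gamma_dot_max`, or both.", call. = FALSE)
  }
  if (is.null(tau_max)) tau_max <- 2 * eta * gamma_dot_max
  if (is.null(gamma_dot_max)) gamma_dot_max <- tau_max / (2 * eta)
  if (any(tau_max < 0) || any(gamma_dot_max < 0)) {
    stop("shear state must be non-negative.", call. = FALSE)
  }
  rel <- abs(tau_max - 2 * eta * gamma_dot_max) /
    pmax(tau_max, 2 * eta * gamma_dot_max, .Machine$double.xmin)
  if (any(rel > 1e-6)) {
    stop("inconsistent shear state: gamma_dot_max must equal tau_max / (2 eta_bl) ",
         "(relative mismatch ", format(max(rel), digits = 3), ").", call. = FALSE)
  }
  tibble::tibble(tau_max = tau_max, gamma_dot_max = gamma_dot_max)
}

#' Full Maxwell-Fricke chain from shear state to principal conductivities
#'
#' Runs, per row of `shear`, the complete scalar model: stress-dependent
#' RBC deformation, shape factor, aligned/random orientation factors, the
#' shear-rate-dependent aligned fraction, the interpolated factors and the
#' two principal conductivities, together with their ratio
#' `lambda_sigma = sigma_alpha / sigma_beta` and the anisotropy indicator
#' `eta_aniso = (sigma_beta - sigma_alpha) / (2 sigma_beta + sigma_alpha)`.
#'
#' @param shear A data frame with columns `tau_max` and/or `gamma_dot_max`
#'   (see [shear_state()]), or a numeric vector of maximum shear rates.
#' @param params A [blood_params()] object.
#' @return A tibble with one row per shear state and columns
#'   `tau_max`, `gamma_dot_max`, `lambda_d`, `M`, `C_a`, `C_b`, `C_r`, `f`,
#'   `C_alpha`, `C_beta`, `sigma_alpha`, `sigma_beta`, `sigma_r`,
#'   `lambda_sigma`, `eta_aniso`.
#' @examples
#' fricke_chain(1.9, blood_params())$lambda_sigma # about 0.77
#' @export
fricke_chain <- function(shear, params = blood_params()) {
  stopifnot(inherits(params, "blood_params"))
  if (is.numeric(shear)) {
    shear <- shear_state(params, gamma_dot_max = shear)
  } else {
    shear <- shear_state(
      params,
      tau_max = if ("tau_max" %in% names(shear)) shear$tau_max else NULL,
      gamma_dot_max = if ("gamma_dot_max" %in% names(shear)) shear$gamma_dot_max else NULL
    )
  }
  lambda_d <- deformed_aspect_ratio(params, shear$tau_max)
  M <- shape_factor(lambda_d)
  ab <- orientation_factors(M)
  C_r <- random_orientation_factor(ab$C_a, ab$C_b)
  f <- aligned_fraction(shear$gamma_dot_max, params$k)
  mixed <- interpolate_orientation_factors(ab$C_a, ab$C_b, C_r, f)
  sigma_alpha <- conductivity_from_factor(mixed$C_alpha, params)
  sigma_beta <- conductivity_from_factor(mixed$C_beta, params)
  tibble::tibble(
    tau_max = shear$tau_max,
    gamma_dot_max = shear$gamma_dot_max,
    lambda_d = lambda_d, M = M,
    C_a = ab$C_a, C_b = ab$C_b, C_r = C_r, f = f,
    C_alpha = mixed$C_alpha, C_beta = mixed$C_beta,
    sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
    sigma_r = conductivity_from_factor(C_r, params),
    lambda_sigma = sigma_alpha / sigma_beta,
    eta_aniso = anisotropy_indicator(sigma_alpha, sigma_beta)
  )
}

#' Principal conductivities of blood at a given shear state
#'
#' Convenience wrapper around [fricke_chain()] returning only the two
#' principal conductivities: `sigma_alpha` along the dominant RBC short-axis
#' direction and `sigma_beta` (twice degenerate) transverse to it. At zero
#' shear both equal the stationary-blood (random-orientation) conductivity;
#' their ratio decreases monotonically with shear rate.
#'
#' @inheritParams fricke_chain
#' @return A tibble with columns `sigma_alpha`, `sigma_beta` (S/m).
#' @examples
#' principal_conductivities(0, blood_params()) # isotropic, about 0.5495 S/m
#' @export
principal_conductivities <- function(shear, params = blood_params()) {
  fricke_chain(shear, params)[, c("sigma_alpha", "sigma_beta")]
}

#' Fully aligned principal conductivities
#'
#' The limit of complete tank-treading alignment (`f = 1`): conductivities
#' computed from the deformed-shape factors `C_a`, `C_b` alone.
#'
#' @param params A [blood_params()] object.
#' @param tau_max Maximum shear stress (Pa, >= 0). Vectorised.
#' @return A tibble with columns `sigma_a`, `sigma_b` (S/m).
#' @export
aligned_conductivities <- function(params, tau_max) {
  lam_d <- deformed_aspect_ratio(params, tau_max)
  ab <- orientation_factors(shape_factor(lam_d))
  tibble::tibble(
    sigma_a = conductivity_from_factor(ab$C_a, params),
    sigma_b = conductivity_from_factor(ab$C_b, params)
  )
}

#' Anisotropy indicator of a transversely isotropic conductivity tensor
#'
#' `eta = (sigma_beta - sigma_alpha) / (2 sigma_beta + sigma_alpha)`: the
#' difference between the largest and smallest principal conductivity over
#' the sum of all three principal values `{sigma_alpha, sigma_beta,
#' sigma_beta}`. Zero iff isotropic; approaches 1/2 as
#' `sigma_alpha/sigma_beta -> 0`.
#'
#' @param sigma_alpha Conductivity along the RBC short-axis direction (S/m).
#' @param sigma_beta Transverse conductivity (S/m). Vectorised.
#' @return Dimensionless indicator in `[0, 1/2)`.
#' @export
anisotropy_indicator <- function(sigma_alpha, sigma_beta) {
  if (any(sigma_alpha <= 0) || any(sigma_beta <= 0)) {
    stop("principal conductivities must be strictly positive.", call. = FALSE)
  }
  (sigma_beta - sigma_alpha) / (2 * sigma_beta + sigma_alpha)
}
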