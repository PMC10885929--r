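#' Rate-of-deformation tensor
#'
#' Symmetric part of the velocity gradient, `D = (G + t(G))/2`, where
#' `G[i, j] = du_i/dx_j` (s^-1). For incompressible flow `trace(D)` should
#' vanish; a warning is issued when `|trace|` exceeds `trace_tol` times the
#' Frobenius norm of `G`.
#'
#' @param grad 3x3 velocity-gradient matrix, `grad[i, j] = du_i/dx_j` (s^-1).
#' @param trace_tol Relative incompressibility tolerance for the warning.
#' @return Symmetric 3x3 matrix (s^-1).
#' @export
rate_of_deformation <- function(grad, trace_tol = 1e-6) {
  grad <- as_matrix3(grad, "grad")
  nrm <- sqrt(sum(grad^2))
  tr <- sum(diag(grad))
  if (nrm > 0 && abs(tr) > trace_tol * nrm) {
    warning("velocity gradient has |trace| = ", format(abs(tr), digits = 3),
            " > ", format(trace_tol, digits = 3),
            " * ||grad||; input may not be incompressible.", call. = FALSE)
  }
  (grad + t(grad)) / 2
}

#' Newtonian viscous stress tensor
#'
#' `tau = 2 * eta_bl * D` for a Newtonian fluid with dynamic viscosity
#' `eta_bl` and rate-of-deformation tensor `D`.
#'
#' @param D Symmetric 3x3 rate-of-deformation matrix (s^-1).
#' @param eta_bl Dynamic viscosity (Pa s).
#' @return Symmetric 3x3 stress matrix (Pa).
#' @export
viscous_stress <- function(D, eta_bl) {
  D <- as_matrix3(D, "D")
  check_symmetric(D, "D")
  2 * eta_bl * D
}

#' Vorticity vector
#'
#' `omega = curl(u)` evaluated from the velocity gradient:
#' `omega_i = eps_ijk du_k/dx_j`.
#'
#' @param grad 3x3 velocity-gradient matrix, `grad[i, j] = du_i/dx_j` (s^-1).
#' @return Length-3 vorticity vector (s^-1).
#' @export
vorticity <- function(grad) {
  grad <- as_matrix3(grad, "grad")
  c(grad[3, 2] - grad[2, 3],
    grad[1, 3] - grad[3, 1],
    grad[2, 1] - grad[1, 2])
}

#' Spectral decomposition of the viscous stress tensor
#'
#' Eigenvalues sorted descending (`tau1 >= tau2 >= tau3`) with orthonormal
#' eigenvectors, plus the maximum shear stress `tau_max = tau1 - tau3` and
#' the maximum shear rate `gamma_dot_max = tau_max / (2 eta_bl)` recovered
#' through the Newtonian constitutive law.
#'
#' @param tau Symmetric 3x3 stress matrix (Pa).
#' @param eta_bl Dynamic viscosity (Pa s) used to convert `tau_max` into
#'   `gamma_dot_max`; `NULL` omits the conversion.
#' @param sym_tol Relative symmetry tolerance.
#' @return A list of class `stress_spectrum`: `values` (descending),
#'   `vectors` (columns `e1`, `e2`, `e3`, sign-normalised), `tau_max`,
#'   `gamma_dot_max` (or `NA` when `eta_bl` is `NULL`).
#' @export
stress_spectrum <- function(tau, eta_bl = NULL, sym_tol = 1e-8) {
  tau <- as_matrix3(tau, "tau")
  check_symmetric(tau, "tau", tol = sym_tol)
  es <- eigen((tau + t(tau)) / 2, symmetric = TRUE)
  vec <- apply(es$vectors, 2, normalize_sign)
  structure(
    list(
      values = es$values,
      vectors = vec,
      tau_max = es$values[1] - es$values[3],
      gamma_dot_max = if (is.null(eta_bl)) NA_real_ else
        (es$values[1] - es$values[3]) / (2 * eta_bl)
    ),
    class = "stress_spectrum"
  )
}

#' RBC short-axis direction from the stress eigenvectors (EV model)
#'
#' The short axis of tank-treading RBCs is taken normal to the plane of
#' maximum shear stress that (mostly) contains the velocity vector. The two
#' candidate normals are `(e1 - e3)/sqrt(2)` and `(e1 + e3)/sqrt(2)`, the
#' 45-degree diagonals between the extreme stress eigenvectors; the one
#' making the larger angle with `u` is selected:
#' `(e1 - e3)/sqrt(2)` when `|<u, (e1 + e3)/sqrt(2)>| > |<u, (e1 - e3)/sqrt(2)>|`,
#' otherwise `(e1 + e3)/sqrt(2)` (ties included).
#'
#' Degeneracy is flagged, never thrown: `zero-stress` when
#' `tau_max < eps_tau`, `repeated-eigenvalue` when the spectrum has a
#' (near-)repeated extreme pair (the axis is still returned when
#' `tau1 - tau3` itself is well separated, since only `e1` and `e3` enter).
#'
#' @param spec A [stress_spectrum()] object.
#' @param u Velocity vector at the point (m/s).
#' @param eps_tau Absolute zero-stress threshold (Pa).
#' @param eps_repeat Relative repeated-eigenvalue threshold.
#' @return A list of class `orientation_axis`: `e_alpha` (unit vector,
#'   sign-normalised, or `NA` when degenerate by zero stress), `model`
#'   (`"EV"`), `degenerate` (`NA` or reason string).
#' @export
eigenvector_axis <- function(spec, u, eps_tau = 1e-12, eps_repeat = 1e-9) {
  stopifnot(inherits(spec, "stress_spectrum"))
  v <- spec$values
  nrm <- max(abs(v))
  degenerate <- NA_character_
  if (spec$tau_max < eps_tau) {
    return(orientation_axis(rep(NA_real_, 3), "EV", "zero-stress"))
  }
  if (min(v[1] - v[2], v[2] - v[3]) < eps_repeat * nrm) {
    degenerate <- "repeated-eigenvalue"
  }
  e1 <- spec$vectors[, 1]
  e3 <- spec$vectors[, 3]
  cand_minus <- (e1 - e3) / sqrt(2)
  cand_plus <- (e1 + e3) / sqrt(2)
  e_alpha <- if (abs(sum(u * cand_plus)) > abs(sum(u * cand_minus))) {
    cand_minus
  } else {
    cand_plus
  }
  orientation_axis(normalize_sign(e_alpha), "EV", degenerate)
}

#' RBC short-axis direction from the Lamb vector (VV model)
#'
#' The short axis is taken along the normalised Lamb vector
#' `u x omega / |u x omega|`, i.e. normal to the plane spanned by the
#' velocity and the vorticity. Degeneracy is flagged (not thrown) when the
#' velocity is (near-)zero (`zero-velocity`) or the cross product is
#' (near-)parallel, `|u x omega| < eps_lamb |u| |omega|`
#' (`parallel-u-omega`, which also covers vanishing vorticity).
#'
#' @param u Velocity vector (m/s).
#' @param omega Vorticity vector (s^-1).
#' @param eps_lamb Relative degeneracy threshold for the cross product.
#' @param eps_u Absolute zero-velocity threshold (m/s).
#' @return An `orientation_axis` list; see [eigenvector_axis()].
#' @export
lamb_axis <- function(u, omega, eps_lamb = 1e-8, eps_u = 1e-30) {
  u <- as.numeric(u); omega <- as.numeric(omega)
  stopifnot(length(u) == 3, length(omega) == 3)
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(omega^2))
  if (nu < eps_u) {
    return(orientation_axis(rep(NA_real_, 3), "VV", "zero-velocity"))
  }
  cp <- cross3(u, omega)
  ncp <- sqrt(sum(cp^2))
  if (nw == 0 || ncp < eps_lamb * nu * nw) {
    return(orientation_axis(rep(NA_real_, 3), "VV", "parallel-u-omega"))
  }
  orientation_axis(normalize_sign(cp / ncp), "VV", NA_character_)
}

orientation_axis <- function(e_alpha, model, degenerate) {
  structure(
    list(e_alpha = e_alpha, model = model, degenerate = degenerate),
    class = "orientation_axis"
  )
}

#' @export
print.orientation_axis <- function(x, ...) {
  cat("<orientation_axis> model =", x$model)
  if (!is.na(x$degenerate)) cat(" [degenerate:", x$degenerate, "]")
  cat("\n  e_alpha =", format(x$e_alpha, digits = 6), "\n")
  invisible(x)
}

#' Assemble the transversely isotropic conductivity tensor
#'
#' `sigma = sigma_alpha (e %o% e) + sigma_beta (I - e %o% e)` with
#' `e = e_alpha`: principal value `sigma_alpha` along the dominant RBC
#' short-axis direction, `sigma_beta` (twice) transverse. Invariant under
#' `e -> -e`. For a degenerate axis the tensor can only be isotropic: if
#' `sigma_alpha == sigma_beta` the isotropic tensor is returned, otherwise
#' an error is thrown (callers wanting the random-orientation fallback pass
#' the `sigma_r` conductivity for both).
#'
#' @param axis An `orientation_axis` (or a bare unit 3-vector).
#' @param sigma_alpha,sigma_beta Principal conductivities (S/m).
#' @return Symmetric positive-definite 3x3 matrix (S/m).
#' @export
assemble_tensor <- function(axis, sigma_alpha, sigma_beta) {
  if (inherits(axis, "orientation_axis")) {
    e <- axis$e_alpha
    if (!is.na(axis$degenerate) && anyNA(e)) {
      if (isTRUE(all.equal(sigma_alpha, sigma_beta))) {
        return(diag(sigma_alpha, 3))
      }
      stop("degenerate orientation axis (", axis$degenerate,
           ") with anisotropic conductivities; use the isotropic fallback.",
           call. = FALSE)
    }
  } else {
    e <- as.numeric(axis)
  }
  stopifnot(length(e) == 3)
  if (abs(sum(e^2) - 1) > 1e-8) stop("`e_alpha` must be a unit vector.", call. = FALSE)
  if (sigma_alpha <= 0 || sigma_beta <= 0) {
    stop("principal conductivities must be strictly positive.", call. = FALSE)
  }
  sigma_beta * diag(3) + (sigma_alpha - sigma_beta) * tcrossprod(e)
}

#' Ohm's law for an anisotropic conductor
#'
#' `J = sigma . E`: current density from the conductivity tensor and the
#' electric field.
#'
#' @param sigma 3x3 conductivity tensor (S/m).
#' @param E Electric field vector (V/m).
#' @return Current density vector (A/m^2).
#' @export
apply_ohm <- function(sigma, E) {
  sigma <- as_matrix3(sigma, "sigma")
  as.numeric(sigma %*% as.numeric(E))
}

# --- internal helpers -------------------------------------------------------

as_matrix3 <- function(m, name) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L)) || any(!is.finite(m))) {
    stop("`", name, "` must be a finite 3x3 matrix.", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

check_symmetric <- function(m, name, tol = 1e-8) {
  nrm <- max(abs(m), .Machine$double.xmin)
  if (max(abs(m - t(m))) > tol * nrm) {
    stop("`", name, "` must be symmetric (relative tolerance ", tol, ").", call. = FALSE)
  }
  invisible(m)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Sign convention: flip so the first component exceeding a small fraction of
# the vector norm is positive. Orientation axes are only defined up to sign;
# a fixed convention makes output reproducible.
normalize_sign <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm) || nrm == 0) return(v)
  i <- which(abs(v) > 1e-12 * nrm)[1]
  if (!is.na(i) && v[i] < 0) -v else v
}
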