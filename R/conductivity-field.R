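degeneracy_labels <- c("zero-stress", "repeated-eigenvalue",
                       "parallel-u-omega", "zero-velocity")

decode_degeneracy <- function(code) {
  out <- rep(NA_character_, length(code))
  hit <- code >= 1 & code <= 4
  out[hit] <- degeneracy_labels[code[hit]]
  out
}

#' Anisotropic conductivity tensor field of a blood flow
#'
#' Maps a velocity field pointwise to the blood conductivity tensor:
#' velocity gradient -> rate of deformation -> Newtonian viscous stress ->
#' stress spectrum (`tau_max = tau1 - tau3`,
#' `gamma_dot_max = tau_max / (2 eta_bl)`) -> RBC orientation axis by the
#' chosen model -> Maxwell-Fricke principal conductivities -> tensor
#' `sigma = sigma_alpha e (x) e + sigma_beta (I - e (x) e)`.
#'
#' At degenerate points (zero stress, or an undefined Lamb vector) no axis
#' exists; the tensor falls back to the isotropic random-orientation
#' conductivity `sigma_r` evaluated at the local `tau_max`, which is the
#' continuous limit since the aligned fraction vanishes with the shear
#' rate. For the VV model at points with finite stress but `u` parallel to
#' `omega`, `vv_fallback = "ev"` substitutes the eigenvector-model axis
#' instead; the point stays flagged either way. Points outside the domain
#' mask (`in_domain = FALSE`) are treated as stationary blood.
#'
#' @param field A [flow_field()].
#' @param params A [blood_params()] object.
#' @param model `"EV"` (viscous-stress eigenvector model) or `"VV"`
#'   (velocity-vorticity / Lamb vector model).
#' @param eps_tau Zero-stress threshold (Pa).
#' @param eps_lamb Relative Lamb-vector degeneracy threshold.
#' @param eps_repeat Relative repeated-eigenvalue threshold.
#' @param vv_fallback `"isotropic"` or `"ev"`: handling of VV-degenerate
#'   points at finite stress.
#' @param trace_tol Relative incompressibility tolerance: a warning reports
#'   the worst `|trace(grad u)| / ||grad u||` beyond it.
#' @return A tibble of class `conductivity_field`: coordinates, `in_domain`,
#'   the six unique tensor components `sxx, syy, szz, sxy, sxz, syz` (S/m),
#'   diagnostics `gamma_dot_max`, `tau_max`, `f_aligned`, `lambda_d`,
#'   `sigma_alpha`, `sigma_beta`, `eta_aniso`, the axis components
#'   `e_alpha_x/y/z` and `degenerate` (reason or `NA`).
#' @examples
#' pipe <- poiseuille_pipe(pipe_spec(0.04, 0.008), n = 9)
#' cf <- conductivity_field(pipe, blood_params(), model = "EV")
#' glance(cf)
#' @export
conductivity_field <- function(field, params = blood_params(),
                               model = c("EV", "VV"),
                               eps_tau = 1e-12, eps_lamb = 1e-8,
                               eps_repeat = 1e-9,
                               vv_fallback = c("isotropic", "ev"),
                               trace_tol = 1e-6) {
  model <- match.arg(model)
  vv_fallback <- match.arg(vv_fallback)
  stopifnot(inherits(params, "blood_params"))
  if (!all(c("x", "y", "z", "ux", "uy", "uz") %in% names(field))) {
    stop("`field` must carry columns x, y, z, ux, uy, uz.", call. = FALSE)
  }
  ker <- stress_axes_field(field, params,
                           eps_tau = eps_tau, eps_lamb = eps_lamb,
                           eps_repeat = eps_repeat, trace_tol = trace_tol)

  in_dom <- if ("in_domain" %in% names(field)) field$in_domain else rep(TRUE, nrow(field))
  tau_eff <- ifelse(in_dom, ker[, "tau_max"], 0)
  chain <- fricke_chain(tibble::tibble(tau_max = tau_eff), params)

  if (model == "EV") {
    e <- ker[, c("ev_x", "ev_y", "ev_z"), drop = FALSE]
    deg <- ker[, "deg_ev"]
  } else {
    e <- ker[, c("vv_x", "vv_y", "vv_z"), drop = FALSE]
    deg <- ker[, "deg_vv"]
    if (vv_fallback == "ev") {
      sub <- deg == 3 & ker[, "deg_ev"] %in% c(0, 2)
      e[sub, ] <- ker[sub, c("ev_x", "ev_y", "ev_z")]
    }
  }
  axis_ok <- !is.na(e[, 1]) & in_dom

  sigma_alpha <- ifelse(axis_ok, chain$sigma_alpha, chain$sigma_r)
  sigma_beta <- ifelse(axis_ok, chain$sigma_beta, chain$sigma_r)

  # sigma = sigma_beta I + (sigma_alpha - sigma_beta) e (x) e
  d <- sigma_alpha - sigma_beta
  ex <- ifelse(axis_ok, e[, 1], 0)
  ey <- ifelse(axis_ok, e[, 2], 0)
  ez <- ifelse(axis_ok, e[, 3], 0)

  out <- tibble::tibble(
    x = field$x, y = field$y, z = field$z,
    in_domain = in_dom,
    sxx = sigma_beta + d * ex * ex,
    syy = sigma_beta + d * ey * ey,
    szz = sigma_beta + d * ez * ez,
    sxy = d * ex * ey,
    sxz = d * ex * ez,
    syz = d * ey * ez,
    gamma_dot_max = ifelse(in_dom, ker[, "gamma_dot_max"], 0),
    tau_max = tau_eff,
    f_aligned = chain$f,
    lambda_d = chain$lambda_d,
    sigma_alpha = sigma_alpha,
    sigma_beta = sigma_beta,
    eta_aniso = anisotropy_indicator(sigma_alpha, sigma_beta),
    e_alpha_x = ifelse(axis_ok, e[, 1], NA_real_),
    e_alpha_y = ifelse(axis_ok, e[, 2], NA_real_),
    e_alpha_z = ifelse(axis_ok, e[, 3], NA_real_),
    degenerate = decode_degeneracy(deg)
  )
  structure(out,
            params = params, model = model,
            axes = attr(field, "axes", exact = TRUE),
            class = c("conductivity_field", class(tibble::tibble())))
}

# Shared kernel driver: gradient + batch stress/axes, with the
# incompressibility diagnostic.
stress_axes_field <- function(field, params, eps_tau = 1e-12,
                              eps_lamb = 1e-8, eps_repeat = 1e-9,
                              trace_tol = 1e-6) {
  grad <- field_gradient(field)
  gm <- as.matrix(grad)
  vel <- as.matrix(field[, c("ux", "uy", "uz")])
  ker <- stress_axes_batch(gm, vel, eta_bl(params),
                           eps_tau, eps_lamb, eps_repeat, 1e-30)
  gnorm <- sqrt(rowSums(gm^2))
  live <- gnorm > 0
  if (any(live)) {
    rel <- abs(ker[live, "trace_D"]) / gnorm[live]
    if (max(rel) > trace_tol) {
      warning("velocity field is not divergence-free: max |trace(grad u)|/||grad u|| = ",
              format(max(rel), digits = 3), call. = FALSE)
    }
  }
  ker
}

#' @export
print.conductivity_field <- function(x, ...) {
  cat("<conductivity_field> model =", attr(x, "model", exact = TRUE),
      "|", nrow(x), "points\n")
  NextMethod()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a conductivity field
#'
#' Statistics are taken over in-domain points; degenerate (axis-undefined)
#' points are counted separately but contribute their isotropic fallback
#' values to the conductivity ranges.
#'
#' @param x A [conductivity_field()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.conductivity_field <- function(x, ...) {
  d <- x[x$in_domain, ]
  tibble::tibble(
    model = attr(x, "model", exact = TRUE),
    n_points = nrow(x),
    n_domain = nrow(d),
    n_degenerate = sum(!is.na(d$degenerate)),
    gamma_dot_max = max(d$gamma_dot_max),
    sigma_alpha_min = min(d$sigma_alpha),
    sigma_beta_max = max(d$sigma_beta),
    eta_aniso_max = max(d$eta_aniso),
    eta_aniso_mean = mean(d$eta_aniso)
  )
}

#' Extract the 3x3 conductivity tensor at one row of a field
#'
#' @param x A [conductivity_field()] (or any data frame with the six
#'   tensor columns).
#' @param i Row index.
#' @return A symmetric 3x3 matrix (S/m).
#' @export
tensor_at <- function(x, i) {
  r <- x[i, ]
  matrix(c(r$sxx, r$sxy, r$sxz,
           r$sxy, r$syy, r$syz,
           r$sxz, r$syz, r$szz), 3, 3)
}
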