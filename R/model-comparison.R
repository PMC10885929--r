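#' Angle between the two model axes
#'
#' `psi_alpha = arccos(|<e_EV, e_VV>|)` in degrees: the angle between the
#' RBC short-axis directions predicted by the stress-eigenvector and the
#' Lamb-vector models. Sign-invariant in both arguments. Evaluated through
#' the algebraically identical form `atan2(||e_EV x e_VV||, |<e_EV, e_VV>|)`,
#' which (unlike a raw arccos, whose resolution degrades to about 2e-6
#' degrees near zero) stays accurate to machine precision for nearly
#' parallel axes.
#'
#' @param e_ev,e_vv Unit 3-vectors, or n x 3 matrices of unit rows.
#' @return Angle(s) in degrees, in `[0, 90]`; `NA` where either axis has a
#'   missing component (degenerate point).
#' @export
psi_alpha <- function(e_ev, e_vv) {
  if (is.null(dim(e_ev))) e_ev <- matrix(e_ev, ncol = 3)
  if (is.null(dim(e_vv))) e_vv <- matrix(e_vv, ncol = 3)
  stopifnot(ncol(e_ev) == 3, ncol(e_vv) == 3, nrow(e_ev) == nrow(e_vv))
  dotp <- abs(rowSums(e_ev * e_vv))
  cx <- e_ev[, 2] * e_vv[, 3] - e_ev[, 3] * e_vv[, 2]
  cy <- e_ev[, 3] * e_vv[, 1] - e_ev[, 1] * e_vv[, 3]
  cz <- e_ev[, 1] * e_vv[, 2] - e_ev[, 2] * e_vv[, 1]
  atan2(sqrt(cx^2 + cy^2 + cz^2), dotp) * 180 / pi
}

#' Angle between two conductivity tensors
#'
#' `psi_sigma = arccos(|<A, B>| / (||A|| ||B||))` in degrees, with the
#' Frobenius inner product `<A, B> = sum_ij A_ij B_ij`. For two transversely
#' isotropic tensors built from the same principal pair the norms are equal,
#' `||A|| = ||B|| = sqrt(sigma_alpha^2 + 2 sigma_beta^2)`; a norm mismatch
#' beyond `1e-9` relative violates that premise and raises an error.
#'
#' Evaluated through the chord form `2 asin(||A/||A|| - B/||B||| / 2)`
#' (identical to the arccos of the normalised inner product for tensors
#' with positive inner product, which positive-definite conductivity
#' tensors always have), so small angles are resolved to machine precision.
#'
#' @param a,b Symmetric 3x3 conductivity matrices (S/m).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
psi_sigma <- function(a, b) {
  a <- as_matrix3(a, "a"); b <- as_matrix3(b, "b")
  check_symmetric(a, "a"); check_symmetric(b, "b")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (abs(na - nb) > 1e-9 * max(na, nb)) {
    stop("tensor norms differ by more than 1e-9 relative; psi_sigma assumes ",
         "both tensors share the same principal conductivities.", call. = FALSE)
  }
  chord <- sqrt(sum((a / na - b / nb)^2))
  2 * asin(min(chord / 2, 1)) * 180 / pi
}

#' Closed-form tensor angle from the axis angle and conductivity ratio
#'
#' For two transversely isotropic tensors sharing principal conductivities
#' `(sigma_alpha, sigma_beta)` with ratio `ls = sigma_alpha / sigma_beta`
#' and axes separated by `psi_alpha`, the tensor angle satisfies
#' `cos(psi_sigma) = (ls^2 c^2 + 2 ls (1 - c^2) + 1 + c^2) / (ls^2 + 2)`
#' with `c = cos(psi_alpha)`. It vanishes at `psi_alpha = 0` or `ls = 1`
#' and is maximal at `psi_alpha = 90` degrees.
#'
#' Internally the identity is rearranged to
#' `sin(psi_sigma / 2) = sin(psi_alpha) (1 - ls) / sqrt(2 (ls^2 + 2))`
#' (using `(ls^2 + 2) - numerator = (1 - c^2)(1 - ls)^2`), which resolves
#' small angles to machine precision where the arccos form saturates.
#'
#' @param lambda_sigma Conductivity ratio in `(0, 1]`. Vectorised.
#' @param psi_alpha_deg Axis angle in degrees, in `[0, 90]`.
#' @return Tensor angle in degrees.
#' @examples
#' psi_sigma_closed_form(0.77, 90) # about 11.6 degrees
#' @export
psi_sigma_closed_form <- function(lambda_sigma, psi_alpha_deg) {
  if (any(lambda_sigma <= 0 | lambda_sigma > 1)) {
    stop("`lambda_sigma` must lie in (0, 1].", call. = FALSE)
  }
  if (any(psi_alpha_deg < 0 | psi_alpha_deg > 90)) {
    stop("`psi_alpha_deg` must lie in [0, 90].", call. = FALSE)
  }
  s <- sin(psi_alpha_deg * pi / 180)
  half_sin <- s * (1 - lambda_sigma) / sqrt(2 * (lambda_sigma^2 + 2))
  2 * asin(pmin(half_sin, 1)) * 180 / pi
}

#' Compare the EV and VV conductivity models over a flow field
#'
#' Runs both orientation models over the same flow and blood parameters and
#' quantifies their disagreement per point: the axis angle `psi_alpha`, the
#' tensor angle `psi_sigma` (computed from the assembled tensors via the
#' Frobenius inner product), and the conductivity ratio `lambda_sigma`.
#' Points where either model is degenerate (or outside the domain) carry
#' `NA` angles and are excluded from the [glance()] summary, which reports
#' them as a count instead.
#'
#' @param field A [flow_field()].
#' @param params A [blood_params()] object.
#' @param ... Passed to [conductivity_field()] (tolerances, `vv_fallback`).
#' @return A tibble of class `model_comparison` with columns `x, y, z`,
#'   `in_domain`, `psi_alpha`, `psi_sigma`, `lambda_sigma`,
#'   `degenerate_ev`, `degenerate_vv`; the two fields are attached as
#'   attributes `field_ev` and `field_vv`.
#' @examples
#' pipe <- poiseuille_pipe(pipe_spec(0.04, 0.008), n = 9)
#' cmp <- compare_models(pipe, blood_params())
#' glance(cmp)
#' @export
compare_models <- function(field, params = blood_params(), ...) {
  f_ev <- conductivity_field(field, params, model = "EV", ...)
  f_vv <- conductivity_field(field, params, model = "VV", ...)
  ok <- f_ev$in_domain & is.na(f_ev$degenerate) & is.na(f_vv$degenerate)

  e_ev <- as.matrix(f_ev[, c("e_alpha_x", "e_alpha_y", "e_alpha_z")])
  e_vv <- as.matrix(f_vv[, c("e_alpha_x", "e_alpha_y", "e_alpha_z")])
  pa <- rep(NA_real_, nrow(f_ev))
  pa[ok] <- psi_alpha(e_ev[ok, , drop = FALSE], e_vv[ok, , drop = FALSE])

  # Frobenius chord angle between the assembled tensors, vectorised; both
  # models share (sigma_alpha, sigma_beta) so the norms agree by
  # construction and the chord form is exact (see psi_sigma()).
  d2 <- (f_ev$sxx - f_vv$sxx)^2 + (f_ev$syy - f_vv$syy)^2 +
    (f_ev$szz - f_vv$szz)^2 +
    2 * ((f_ev$sxy - f_vv$sxy)^2 + (f_ev$sxz - f_vv$sxz)^2 +
           (f_ev$syz - f_vv$syz)^2)
  nrm <- sqrt(f_ev$sigma_alpha^2 + 2 * f_ev$sigma_beta^2)
  ps <- rep(NA_real_, nrow(f_ev))
  ps[ok] <- 2 * asin(pmin(sqrt(d2[ok]) / (2 * nrm[ok]), 1)) * 180 / pi

  out <- tibble::tibble(
    x = f_ev$x, y = f_ev$y, z = f_ev$z,
    in_domain = f_ev$in_domain,
    psi_alpha = pa,
    psi_sigma = ps,
    lambda_sigma = f_ev$sigma_alpha / f_ev$sigma_beta,
    degenerate_ev = f_ev$degenerate,
    degenerate_vv = f_vv$degenerate
  )
  structure(out,
            params = params,
            field_ev = f_ev, field_vv = f_vv,
            class = c("model_comparison", class(tibble::tibble())))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>", nrow(x), "points\n")
  NextMethod()
}

#' Per-point comparison records
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return The underlying tibble of per-point records.
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summary of the EV/VV model disagreement
#'
#' Angle statistics over in-domain, non-degenerate points; degenerate points
#' are counted, not averaged. Also reports the minimum conductivity ratio
#' and the closed-form worst-case tensor angle
#' `psi_sigma_closed_form(min lambda_sigma, 90)` implied by it.
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.model_comparison <- function(x, ...) {
  d <- x[x$in_domain, ]
  ok <- !is.na(d$psi_alpha)
  q <- stats::quantile(d$psi_alpha[ok], c(0.5, 0.95), names = FALSE)
  ls_min <- min(d$lambda_sigma)
  tibble::tibble(
    n_domain = nrow(d),
    n_degenerate = sum(!ok),
    frac_degenerate = mean(!ok),
    psi_alpha_max = max(d$psi_alpha[ok]),
    psi_alpha_mean = mean(d$psi_alpha[ok]),
    psi_alpha_median = q[1],
    psi_alpha_q95 = q[2],
    psi_sigma_max = max(d$psi_sigma[ok]),
    psi_sigma_mean = mean(d$psi_sigma[ok]),
    lambda_sigma_min = ls_min,
    psi_sigma_bound = psi_sigma_closed_form(ls_min, 90)
  )
}
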