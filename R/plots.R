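#' Plot the aligned-fraction law
#'
#' The fraction of tank-treading (aligned) RBCs against the maximum shear
#' rate, with the low/high alignment boundaries (f = 0.20 and 0.80) marked.
#'
#' @param params A [blood_params()] (supplies `k`).
#' @param gamma_max Upper end of the shear-rate axis (s^-1).
#' @return A ggplot object.
#' @export
plot_alignment_fraction <- function(params = blood_params(), gamma_max = 50) {
  g <- seq(0, gamma_max, length.out = 400)
  df <- tibble::tibble(gamma_dot_max = g,
                       f = aligned_fraction(g, params$k))
  marks <- tibble::tibble(
    f = c(0.20, 0.80),
    gamma_dot_max = alignment_shear_rate(c(0.20, 0.80), params$k)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma_dot_max, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(0.2, 0.8), linetype = "dotted") +
    ggplot2::labs(x = expression(dot(gamma)[max] ~ (s^-1)),
                  y = "fraction of aligned RBCs f") +
    ggplot2::theme_minimal()
}

#' Radial conductivity profile of a pipe conductivity field
#'
#' Principal conductivities and the anisotropy indicator against the radial
#' coordinate `r = sqrt(x^2 + y^2)`, over in-domain points.
#'
#' @param cfield A [conductivity_field()] computed on a pipe flow.
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(cfield) {
  d <- tibble::as_tibble(cfield)
  d <- d[d$in_domain, ]
  d$r <- sqrt(d$x^2 + d$y^2)
  long <- tidyr::pivot_longer(
    d[, c("r", "sigma_alpha", "sigma_beta", "eta_aniso")],
    cols = -"r", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "r (m)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Mid-plane maps of a conductivity field
#'
#' Heatmaps of the anisotropy indicator and `sigma_alpha` on the axial
#' mid-plane of the grid.
#'
#' @param object A [conductivity_field()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conductivity_field <- function(object, ...) {
  d <- tibble::as_tibble(object)
  zmid <- sort(unique(d$z))
  zmid <- zmid[ceiling(length(zmid) / 2)]
  d <- d[d$z == zmid & d$in_domain, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$eta_aniso)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = expression(eta)) +
    ggplot2::labs(title = paste("anisotropy indicator,", attr(object, "model"), "model"),
                  x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Histogram of the EV/VV disagreement angles
#'
#' @param object A [compare_models()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$in_domain & !is.na(d$psi_alpha), ]
  long <- tidyr::pivot_longer(d[, c("psi_alpha", "psi_sigma")],
                              cols = dplyr::everything(),
                              names_to = "angle", values_to = "degrees")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$degrees)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::facet_wrap(~angle, scales = "free") +
    ggplot2::labs(x = "angle (degrees)", y = "points") +
    ggplot2::theme_minimal()
}
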