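#' Construct a flow field on a structured Cartesian grid
#'
#' A flow field is a tibble with one row per grid point, columns
#' `x, y, z` (m), `ux, uy, uz` (m/s) and a logical `in_domain` marking
#' points inside the physical domain (e.g. inside a vessel lumen). Points
#' are stored in VTK order: `x` varies fastest, then `y`, then `z`. The
#' grid axes and, when available, an analytic velocity-gradient closure are
#' attached as attributes so downstream computations can avoid
#' finite differences.
#'
#' @param axes A list with strictly monotone numeric vectors `x`, `y`, `z`
#'   (grid coordinates, m).
#' @param velocity A function `f(df)` receiving the coordinate tibble and
#'   returning a data frame/list with `ux, uy, uz`, or a data frame with
#'   those columns in grid order.
#' @param gradient A function `f(df)` returning the nine gradient columns
#'   `dux_dx, dux_dy, dux_dz, duy_dx, ..., duz_dz` (s^-1) at the rows of
#'   `df`, or `NULL` if only finite differences are available.
#' @param in_domain Logical vector (or function of the coordinate tibble);
#'   defaults to all `TRUE`.
#' @return A tibble of class `flow_field`.
#' @export
flow_field <- function(axes, velocity, gradient = NULL, in_domain = TRUE) {
  axes <- lapply(axes[c("x", "y", "z")], as.numeric)
  for (ax in c("x", "y", "z")) {
    v <- axes[[ax]]
    if (length(v) < 1 || any(!is.finite(v)) || is.unsorted(v, strictly = TRUE)) {
      stop("grid axis `", ax, "` must be finite and strictly increasing.", call. = FALSE)
    }
  }
  pts <- tidyr::expand_grid(z = axes$z, y = axes$y, x = axes$x)
  pts <- pts[, c("x", "y", "z")]
  vel <- if (is.function(velocity)) tibble::as_tibble(velocity(pts)) else tibble::as_tibble(velocity)
  if (!all(c("ux", "uy", "uz") %in% names(vel)) || nrow(vel) != nrow(pts)) {
    stop("`velocity` must provide columns ux, uy, uz for every grid point.", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(vel[, c("ux", "uy", "uz")])))) {
    stop("velocities must be finite everywhere.", call. = FALSE)
  }
  dom <- if (is.function(in_domain)) in_domain(pts) else rep_len(in_domain, nrow(pts))
  out <- dplyr::bind_cols(pts, vel[, c("ux", "uy", "uz")])
  out$in_domain <- as.logical(dom)
  new_flow_field(out, axes = axes, gradient = gradient)
}

new_flow_field <- function(df, axes, gradient = NULL) {
  structure(
    tibble::as_tibble(df),
    axes = axes,
    gradient = gradient,
    class = c("flow_field", class(tibble::tibble()))
  )
}

#' Grid axes of a flow field
#' @param field A [flow_field()].
#' @return A list with the numeric axes `x`, `y`, `z`.
#' @export
field_axes <- function(field) {
  ax <- attr(field, "axes", exact = TRUE)
  if (is.null(ax)) stop("not a structured flow field: missing `axes` attribute.", call. = FALSE)
  ax
}

#' Specification of a (possibly swirling) pipe flow
#'
#' @param diameter Vessel diameter D (m, > 0).
#' @param u_mean Mean (bulk) axial velocity (m/s, > 0).
#' @param swirl_rate Swirl amplitude Omega (s^-1, >= 0); 0 gives a pure
#'   Poiseuille flow.
#' @param length Axial extent of the generated grid (m); defaults to the
#'   diameter.
#' @return A list of class `pipe_spec`.
#' @export
pipe_spec <- function(diameter, u_mean, swirl_rate = 0, length = diameter) {
  stopifnot(diameter > 0, u_mean > 0, swirl_rate >= 0, length > 0)
  structure(list(diameter = diameter, u_mean = u_mean,
                 swirl_rate = swirl_rate, length = length),
            class = "pipe_spec")
}

#' Analytic Poiseuille pipe flow
#'
#' Fully developed laminar flow in a straight rigid pipe of diameter `D`
#' along the +z axis: `uz(r) = 2 u_mean (1 - (2r/D)^2)` for `r <= D/2`, zero
#' at the wall (no slip) and outside the lumen. The centreline velocity is
#' `2 u_mean` and the wall shear rate `8 u_mean / D`. The returned field
#' carries an exact analytic gradient closure.
#'
#' Grid points with `r > D/2` lie outside the vessel and are marked
#' `in_domain = FALSE` (velocity and gradient zero there).
#'
#' @param spec A [pipe_spec()] with `swirl_rate = 0`.
#' @param n Number of grid points per transverse axis (>= 3).
#' @param nz Number of axial grid points (>= 3); defaults to `n`.
#' @return A [flow_field()] tibble.
#' @examples
#' pipe <- poiseuille_pipe(pipe_spec(0.04, 0.008), n = 9)
#' max(pipe$uz) # centreline velocity 2 * u_mean
#' @export
poiseuille_pipe <- function(spec, n = 33, nz = n) {
  stopifnot(inherits(spec, "pipe_spec"))
  if (spec$swirl_rate != 0) {
    stop("`spec$swirl_rate` must be 0 for a Poiseuille pipe; see swirling_pipe().", call. = FALSE)
  }
  swirling_pipe(spec, n = n, nz = nz)
}

#' Analytic swirling pipe flow
#'
#' Superposes onto the Poiseuille profile an axially modulated azimuthal
#' velocity
#' `u_theta(r, z) = Omega * r * (1 - (2r/D)^2) * cos(2 pi z / L)`,
#' which is divergence-free for any modulation, respects no slip at the
#' wall, and reduces continuously to [poiseuille_pipe()] at `Omega = 0`.
#' The axial modulation gives the vorticity a radial component, so velocity
#' and stress eigenstructure decouple: this is the canonical in-package flow
#' in which the stress-eigenvector and Lamb-vector orientation models
#' genuinely disagree. (A pure solid-body swirl `u_theta = Omega r` would
#' not do: for any axisymmetric `u_theta(r), uz(r)` both model axes remain
#' exactly radial.) At the origin the vorticity is `(0, 0, 2 Omega)`.
#'
#' @param spec A [pipe_spec()]; `swirl_rate` is Omega, `length` the axial
#'   grid extent and modulation wavelength L.
#' @param n Number of grid points per transverse axis (>= 3).
#' @param nz Number of axial grid points (>= 3); defaults to `n`.
#' @return A [flow_field()] tibble with analytic gradient closure.
#' @export
swirling_pipe <- function(spec, n = 33, nz = n) {
  stopifnot(inherits(spec, "pipe_spec"))
  if (n < 3 || nz < 3) stop("pipe grids need at least 3 points per axis.", call. = FALSE)
  D <- spec$diameter
  um <- spec$u_mean
  Om <- spec$swirl_rate
  L <- spec$length
  R <- D / 2
  axes <- list(
    x = seq(-R, R, length.out = n),
    y = seq(-R, R, length.out = n),
    z = seq(0, L, length.out = nz)
  )

  velocity <- function(df) {
    r2 <- df$x^2 + df$y^2
    inside <- r2 <= R^2
    para <- 1 - 4 * r2 / D^2
    h <- cos(2 * pi * df$z / L)
    s <- ifelse(inside, Om * para * h, 0) # u_theta / r
    tibble::tibble(
      ux = -df$y * s,
      uy = df$x * s,
      uz = ifelse(inside, 2 * um * para, 0)
    )
  }

  gradient <- function(df) {
    r2 <- df$x^2 + df$y^2
    inside <- as.numeric(r2 <= R^2)
    h <- cos(2 * pi * df$z / L)
    hp <- -(2 * pi / L) * sin(2 * pi * df$z / L)
    para <- 1 - 4 * r2 / D^2
    c8 <- 8 * Om / D^2
    tibble::tibble(
      dux_dx = inside * (c8 * df$x * df$y * h),
      dux_dy = inside * (-Om * para * h + c8 * df$y^2 * h),
      dux_dz = inside * (-df$y * Om * para * hp),
      duy_dx = inside * (Om * para * h - c8 * df$x^2 * h),
      duy_dy = inside * (-c8 * df$x * df$y * h),
      duy_dz = inside * (df$x * Om * para * hp),
      duz_dx = inside * (-16 * um * df$x / D^2),
      duz_dy = inside * (-16 * um * df$y / D^2),
      duz_dz = 0
    )
  }

  in_domain <- function(df) df$x^2 + df$y^2 <= R^2
  fl <- flow_field(axes, velocity, gradient, in_domain)
  attr(fl, "pipe_spec") <- spec
  fl
}

#' Random divergence-free velocity field
#'
#' Generates a smooth random field as the curl of a random trigonometric
#' vector potential, so the velocity is solenoidal analytically (finite
#' difference divergence converges to zero at second order under grid
#' refinement). Reproducible for a given seed; amplitude 0 gives the zero
#' field. An exact analytic gradient closure is attached.
#'
#' @param seed Integer seed for the mode coefficients.
#' @param box Numeric length-3 box edge lengths (m).
#' @param n Grid points per axis (>= 3).
#' @param n_modes Number of random Fourier modes of the vector potential.
#' @param max_wavenumber Largest integer wavenumber per component; smaller
#'   values give smoother fields.
#' @param amplitude Velocity scale (m/s).
#' @return A [flow_field()] tibble.
#' @export
random_solenoidal_field <- function(seed, box = c(1, 1, 1), n = 9,
                                    n_modes = 6, max_wavenumber = 2,
                                    amplitude = 1) {
  stopifnot(length(box) == 3, all(box > 0), amplitude >= 0, n >= 3,
            n_modes >= 1, max_wavenumber >= 1)
  modes <- withr::with_seed(as.integer(seed), {
    list(
      # integer wavevectors, at least one nonzero component each
      k = matrix(sample(seq(-max_wavenumber, max_wavenumber),
                        3 * n_modes, replace = TRUE), ncol = 3),
      coef = matrix(stats::rnorm(3 * n_modes), ncol = 3),
      phase = matrix(stats::runif(3 * n_modes, 0, 2 * pi), ncol = 3)
    )
  })
  zero <- rowSums(abs(modes$k)) == 0
  modes$k[zero, 1] <- 1L
  kappa <- sweep(modes$k, 2, 2 * pi / box, `*`) # physical wavevectors

  # A_j(x) = amplitude * sum_m coef[m, j] sin(kappa_m . x + phase[m, j])
  # u = curl A, grad u analytic from second derivatives of A.
  eval_modes <- function(df, deriv) {
    npt <- nrow(df)
    u <- matrix(0, npt, 3)
    g <- matrix(0, npt, 9) # row-major du_i/dx_j
    X <- cbind(df$x, df$y, df$z)
    for (m in seq_len(nrow(kappa))) {
      kx <- as.numeric(X %*% kappa[m, ])
      for (j in 1:3) {
        arg <- kx + modes$phase[m, j]
        cj <- amplitude * modes$coef[m, j]
        # dA_j/dx_l = cj * kappa[m, l] * cos(arg)
        # d2A_j/dx_l dx_q = -cj * kappa[m, l] * kappa[m, q] * sin(arg)
        co <- cj * cos(arg)
        si <- cj * sin(arg)
        # curl: u1 += dA3/dy - dA2/dz etc., accumulate per j
        if (j == 3) {
          u[, 1] <- u[, 1] + kappa[m, 2] * co
          g[, 1] <- g[, 1] - kappa[m, 2] * kappa[m, 1] * si
          g[, 2] <- g[, 2] - kappa[m, 2] * kappa[m, 2] * si
          g[, 3] <- g[, 3] - kappa[m, 2] * kappa[m, 3] * si
          u[, 2] <- u[, 2] - kappa[m, 1] * co
          g[, 4] <- g[, 4] + kappa[m, 1] * kappa[m, 1] * si
          g[, 5] <- g[, 5] + kappa[m, 1] * kappa[m, 2] * si
          g[, 6] <- g[, 6] + kappa[m, 1] * kappa[m, 3] * si
        } else if (j == 2) {
          u[, 1] <- u[, 1] - kappa[m, 3] * co
          g[, 1] <- g[, 1] + kappa[m, 3] * kappa[m, 1] * si
          g[, 2] <- g[, 2] + kappa[m, 3] * kappa[m, 2] * si
          g[, 3] <- g[, 3] + kappa[m, 3] * kappa[m, 3] * si
          u[, 3] <- u[, 3] + kappa[m, 1] * co
          g[, 7] <- g[, 7] - kappa[m, 1] * kappa[m, 1] * si
          g[, 8] <- g[, 8] - kappa[m, 1] * kappa[m, 2] * si
          g[, 9] <- g[, 9] - kappa[m, 1] * kappa[m, 3] * si
        } else {
          u[, 2] <- u[, 2] + kappa[m, 3] * co
          g[, 4] <- g[, 4] - kappa[m, 3] * kappa[m, 1] * si
          g[, 5] <- g[, 5] - kappa[m, 3] * kappa[m, 2] * si
          g[, 6] <- g[, 6] - kappa[m, 3] * kappa[m, 3] * si
          u[, 3] <- u[, 3] - kappa[m, 2] * co
          g[, 7] <- g[, 7] + kappa[m, 2] * kappa[m, 1] * si
          g[, 8] <- g[, 8] + kappa[m, 2] * kappa[m, 2] * si
          g[, 9] <- g[, 9] + kappa[m, 2] * kappa[m, 3] * si
        }
      }
    }
    if (deriv) {
      colnames(g) <- gradient_cols()
      tibble::as_tibble(g)
    } else {
      tibble::tibble(ux = u[, 1], uy = u[, 2], uz = u[, 3])
    }
  }

  axes <- list(
    x = seq(0, box[1], length.out = n),
    y = seq(0, box[2], length.out = n),
    z = seq(0, box[3], length.out = n)
  )
  flow_field(axes,
             velocity = function(df) eval_modes(df, deriv = FALSE),
             gradient = function(df) eval_modes(df, deriv = TRUE))
}

#' Uniform flow field
#'
#' A constant velocity everywhere (zero gradient): the simplest degenerate
#' benchmark, for which the conductivity field must be isotropic at the
#' stationary-blood value.
#'
#' @param u Length-3 constant velocity vector (m/s).
#' @param box Numeric length-3 box edge lengths (m).
#' @param n Grid points per axis.
#' @return A [flow_field()] tibble.
#' @export
uniform_flow <- function(u = c(0.01, 0, 0), box = c(1, 1, 1), n = 5) {
  stopifnot(length(u) == 3)
  axes <- list(
    x = seq(0, box[1], length.out = n),
    y = seq(0, box[2], length.out = n),
    z = seq(0, box[3], length.out = n)
  )
  flow_field(
    axes,
    velocity = function(df) tibble::tibble(
      ux = rep(u[1], nrow(df)), uy = rep(u[2], nrow(df)), uz = rep(u[3], nrow(df))
    ),
    gradient = function(df) {
      g <- matrix(0, nrow(df), 9, dimnames = list(NULL, gradient_cols()))
      tibble::as_tibble(g)
    }
  )
}

gradient_cols <- function() {
  c("dux_dx", "dux_dy", "dux_dz",
    "duy_dx", "duy_dy", "duy_dz",
    "duz_dx", "duz_dy", "duz_dz")
}

#' Finite-difference velocity gradient on a structured grid
#'
#' Second-order central differences in the interior and second-order
#' one-sided stencils at the boundaries, on (possibly non-uniform) strictly
#' monotone axes. Exact for velocity fields that are polynomials of degree
#' <= 2 per direction (interior).
#'
#' @param field A [flow_field()] with at least 3 points per axis.
#' @return A tibble with the nine columns `dux_dx ... duz_dz` (s^-1), rows
#'   aligned with `field`.
#' @export
fd_gradient <- function(field) {
  ax <- field_axes(field)
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  if (min(nx, ny, nz) < 3) {
    stop("fd_gradient needs at least 3 grid points per axis.", call. = FALSE)
  }
  if (nrow(field) != nx * ny * nz) {
    stop("field rows do not match the grid (expected ", nx * ny * nz, ").", call. = FALSE)
  }
  out <- matrix(0, nrow(field), 9, dimnames = list(NULL, gradient_cols()))
  for (ci in 1:3) {
    comp <- c("ux", "uy", "uz")[ci]
    arr <- array(field[[comp]], dim = c(nx, ny, nz))
    out[, 3 * (ci - 1) + 1] <- as.vector(fd_deriv_axis(arr, ax$x, 1))
    out[, 3 * (ci - 1) + 2] <- as.vector(fd_deriv_axis(arr, ax$y, 2))
    out[, 3 * (ci - 1) + 3] <- as.vector(fd_deriv_axis(arr, ax$z, 3))
  }
  tibble::as_tibble(out)
}

# d(arr)/d(coord) along dimension `dim` of a 3D array, 2nd order everywhere.
fd_deriv_axis <- function(arr, coords, dim) {
  n <- length(coords)
  slice <- function(i) {
    switch(dim, arr[i, , , drop = FALSE], arr[, i, , drop = FALSE], arr[, , i, drop = FALSE])
  }
  out <- array(0, dim = dim(arr))
  assign_slice <- function(i, val) {
    switch(dim,
           out[i, , ] <<- val,
           out[, i, ] <<- val,
           out[, , i] <<- val)
  }
  # interior: non-uniform 3-point central
  for (i in 2:(n - 1)) {
    h1 <- coords[i] - coords[i - 1]
    h2 <- coords[i + 1] - coords[i]
    w_m <- -h2 / (h1 * (h1 + h2))
    w_0 <- (h2 - h1) / (h1 * h2)
    w_p <- h1 / (h2 * (h1 + h2))
    assign_slice(i, w_m * slice(i - 1) + w_0 * slice(i) + w_p * slice(i + 1))
  }
  # boundaries: 3-point one-sided, 2nd order
  h1 <- coords[2] - coords[1]; h2 <- coords[3] - coords[2]
  assign_slice(1,
               -(2 * h1 + h2) / (h1 * (h1 + h2)) * slice(1) +
                 (h1 + h2) / (h1 * h2) * slice(2) -
                 h1 / (h2 * (h1 + h2)) * slice(3))
  h1 <- coords[n] - coords[n - 1]; h2 <- coords[n - 1] - coords[n - 2]
  assign_slice(n,
               (2 * h1 + h2) / (h1 * (h1 + h2)) * slice(n) -
                 (h1 + h2) / (h1 * h2) * slice(n - 1) +
                 h1 / (h2 * (h1 + h2)) * slice(n - 2))
  out
}

#' Velocity gradient of a flow field
#'
#' Returns the analytic gradient closure when the field carries one,
#' otherwise falls back to [fd_gradient()].
#'
#' @param field A [flow_field()].
#' @return A tibble with the nine columns `dux_dx ... duz_dz` (s^-1).
#' @export
field_gradient <- function(field) {
  g <- attr(field, "gradient", exact = TRUE)
  if (is.function(g)) {
    res <- tibble::as_tibble(g(field))
    if (!all(gradient_cols() %in% names(res))) {
      stop("analytic gradient closure must return the nine columns ",
           paste(gradient_cols(), collapse = ", "), ".", call. = FALSE)
    }
    res[, gradient_cols()]
  } else {
    fd_gradient(field)
  }
}
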