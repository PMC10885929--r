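# Shared fixtures and small oracles, all built in code.

default_params <- blood_params()

# Benchmark straight-vessel case: D = 0.04 m, u_mean = 0.008 m/s.
bench_pipe_spec <- pipe_spec(0.04, 0.008)

small_pipe <- function(n = 13) poiseuille_pipe(bench_pipe_spec, n = n)

small_swirl <- function(n = 13, omega = 2) {
  swirling_pipe(pipe_spec(0.04, 0.008, swirl_rate = omega), n = n)
}

# Random rotation matrix (Haar-ish via QR, determinant forced to +1).
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q %*% diag(c(1, 1, det(q)))
}

# Random symmetric traceless 3x3 (a plausible incompressible-stress shape).
random_traceless_sym <- function(scale = 1) {
  a <- matrix(stats::rnorm(9, sd = scale), 3, 3)
  s <- (a + t(a)) / 2
  s - diag(sum(diag(s)) / 3, 3)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

angle_deg <- function(a, b) psi_alpha(a, b)

# A single-point "flow field": constant velocity with a constant analytic
# gradient closure, for exercising the field pipeline on hand-built
# kinematics.
point_flow <- function(u, G, n = 3L) {
  axes <- list(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  flow_field(
    axes,
    velocity = function(df) tibble::tibble(
      ux = rep(u[1], nrow(df)), uy = rep(u[2], nrow(df)), uz = rep(u[3], nrow(df))
    ),
    gradient = function(df) {
      g <- matrix(rep(as.numeric(t(G)), each = nrow(df)), nrow = nrow(df))
      colnames(g) <- hemocond:::gradient_cols()
      tibble::as_tibble(g)
    }
  )
}
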