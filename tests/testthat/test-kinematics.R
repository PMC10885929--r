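# Pointwise kinematics: rate of deformation, stress spectrum, and the two
# orientation-axis constructions.

test_that("rate of deformation extracts the symmetric part", {
  W <- matrix(c(0, 1, -2, -1, 0, 3, 2, -3, 0), 3, 3) # antisymmetric
  expect_equal(rate_of_deformation(W), matrix(0, 3, 3))
  G <- matrix(0, 3, 3); G[1, 2] <- 1.7 # simple shear du_x/dy
  D <- rate_of_deformation(G)
  expect_equal(D, matrix(c(0, 0.85, 0, 0.85, 0, 0, 0, 0, 0), 3, 3))
  S <- random_traceless_sym()
  expect_equal(rate_of_deformation(S), S)
  expect_warning(rate_of_deformation(diag(c(1, 1, 1))), "incompressible")
})

test_that("viscous stress is the linear Newtonian law", {
  expect_equal(viscous_stress(matrix(0, 3, 3), 0.05), matrix(0, 3, 3))
  G <- matrix(0, 3, 3); G[1, 2] <- 2 # shear rate 2
  tau <- viscous_stress(rate_of_deformation(G), 0.05)
  expect_equal(tau[1, 2], 0.05 * 2) # tau_xy = eta * gdot
  D <- random_traceless_sym()
  expect_equal(viscous_stress(3 * D, 0.04), 3 * viscous_stress(D, 0.04))
})

test_that("vorticity is the curl of the velocity field", {
  G <- matrix(0, 3, 3); G[1, 2] <- 1.3 # u = (1.3 y, 0, 0)
  expect_equal(vorticity(G), c(0, 0, -1.3))
  Om <- 0.7 # solid-body rotation about z
  G <- matrix(c(0, -Om, 0, Om, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(vorticity(G), c(0, 0, 2 * Om))
  expect_equal(vorticity(random_traceless_sym()), c(0, 0, 0))
})

test_that("stress spectrum sorts eigenvalues and yields tau_max = tau1 - tau3", {
  s <- 0.3
  tau <- matrix(c(0, s, 0, s, 0, 0, 0, 0, 0), 3, 3)
  sp <- stress_spectrum(tau, eta_bl = 0.05)
  expect_equal(sp$values, c(s, 0, -s))
  expect_equal(sp$tau_max, 2 * s)
  expect_equal(sp$gamma_dot_max, 2 * s / (2 * 0.05))
  expect_equal(crossprod(sp$vectors), diag(3), tolerance = 1e-10)
  # isotropic pressure: degenerate spectrum, no shear
  sp2 <- stress_spectrum(diag(0.2, 3))
  expect_equal(sp2$tau_max, 0)
  expect_error(stress_spectrum(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
})

test_that("tau_max agrees with a brute-force search over shear planes", {
  # the maximum shear component over all orthonormal pairs (n, m) is
  # (tau1 - tau3)/2; scan random orientations as an independent oracle
  set.seed(42)
  for (rep in 1:5) {
    tau <- random_traceless_sym(scale = 0.2)
    sp <- stress_spectrum(tau)
    best <- 0
    for (i in 1:4000) {
      R <- random_rotation()
      best <- max(best, abs(t(R[, 1]) %*% tau %*% R[, 2]))
    }
    # random sampling undershoots the true maximum slightly
    expect_equal(2 * best, sp$tau_max, tolerance = 0.02)
    expect_lte(2 * best, sp$tau_max * (1 + 1e-12))
  }
})

test_that("EV axis picks the shear-plane normal at the larger angle to u", {
  # simple shear u = (g y, 0, 0): candidates are ex and ey; velocity along
  # ex forces the normal to ey
  g <- 1.6
  G <- matrix(0, 3, 3); G[1, 2] <- g
  tau <- viscous_stress(rate_of_deformation(G), 0.05)
  sp <- stress_spectrum(tau, 0.05)
  ax <- eigenvector_axis(sp, u = c(g * 0.01, 0, 0))
  expect_true(is.na(ax$degenerate))
  expect_equal(abs(ax$e_alpha), c(0, 1, 0), tolerance = 1e-12)
  # tie (u parallel to e2, orthogonal to both candidates): the
  # "otherwise" branch returns (e1 + e3)/sqrt(2) as written
  ax_tie <- eigenvector_axis(sp, u = c(0, 0, 1))
  cand_plus <- (sp$vectors[, 1] + sp$vectors[, 3]) / sqrt(2)
  expect_equal(abs(sum(ax_tie$e_alpha * cand_plus)), 1, tolerance = 1e-12)
})

test_that("EV degeneracies are flagged, not thrown", {
  sp0 <- stress_spectrum(matrix(0, 3, 3))
  ax0 <- eigenvector_axis(sp0, u = c(1, 0, 0))
  expect_equal(ax0$degenerate, "zero-stress")
  expect_true(anyNA(ax0$e_alpha))
  # repeated extreme eigenvalue with well separated tau1 - tau3:
  # flagged but the axis is still computed from e1 and e3
  spr <- stress_spectrum(diag(c(1, 1, 0)))
  axr <- eigenvector_axis(spr, u = c(0, 0, 1))
  expect_equal(axr$degenerate, "repeated-eigenvalue")
  expect_false(anyNA(axr$e_alpha))
  expect_equal(sqrt(sum(axr$e_alpha^2)), 1, tolerance = 1e-12)
})

test_that("Lamb axis is the normalised u x omega with flagged degeneracies", {
  g <- 1.6
  u <- c(g * 0.01, 0, 0)
  omega <- c(0, 0, -g) # vorticity of the simple shear
  ax <- lamb_axis(u, omega)
  expect_equal(ax$e_alpha, c(0, 1, 0), tolerance = 1e-14) # agrees with EV
  expect_equal(lamb_axis(c(1, 1, 0), c(2, 2, 0))$degenerate, "parallel-u-omega")
  expect_equal(lamb_axis(c(0, 0, 0), c(1, 0, 0))$degenerate, "zero-velocity")
  expect_equal(lamb_axis(c(1, 0, 0), c(0, 0, 0))$degenerate, "parallel-u-omega")
})

test_that("assembled tensor has spectrum {sigma_alpha, sigma_beta, sigma_beta} and the right axis", {
  expect_equal(assemble_tensor(c(0, 0, 1), 0.4, 0.4), diag(0.4, 3))
  expect_equal(assemble_tensor(c(0, 0, 1), 0.3, 0.5), diag(c(0.5, 0.5, 0.3)))
  set.seed(7)
  for (i in 1:20) {
    e <- unit_vec(rnorm(3))
    sa <- runif(1, 0.1, 0.5); sb <- runif(1, sa, 0.7)
    S <- assemble_tensor(e, sa, sb)
    expect_equal(S, t(S))
    es <- eigen(S, symmetric = TRUE)
    expect_equal(sort(es$values), sort(c(sa, sb, sb)), tolerance = 1e-9)
    i_min <- which.min(es$values)
    expect_equal(abs(sum(es$vectors[, i_min] * e)), 1, tolerance = 1e-9)
    expect_equal(assemble_tensor(-e, sa, sb), S) # sign invariance
  }
})

test_that("degenerate axes only assemble isotropically", {
  deg <- hemocond:::orientation_axis(rep(NA_real_, 3), "EV", "zero-stress")
  expect_equal(assemble_tensor(deg, 0.55, 0.55), diag(0.55, 3))
  expect_error(assemble_tensor(deg, 0.4, 0.6), "isotropic fallback")
})

test_that("Ohm's law maps the tensor eigen-directions correctly", {
  e <- unit_vec(c(1, 2, -1))
  S <- assemble_tensor(e, 0.3, 0.6)
  expect_equal(apply_ohm(S, 2 * e), 0.3 * 2 * e)
  perp <- unit_vec(cross_test <- c(2, -1, 0)) # orthogonal to e
  expect_equal(sum(perp * e), 0)
  expect_equal(apply_ohm(S, perp), 0.6 * perp)
  expect_equal(apply_ohm(diag(0.5, 3), c(1, -2, 3)), 0.5 * c(1, -2, 3))
})

test_that("anisotropy indicator spans [0, 1/2) and matches the chain value", {
  expect_equal(anisotropy_indicator(0.5, 0.5), 0)
  expect_equal(anisotropy_indicator(1e-12, 0.5), 0.5, tolerance = 1e-9)
  expect_equal(anisotropy_indicator(0.461428679896338, 0.599270685916343),
               0.083038851138566, tolerance = 1e-10)
})

test_that("both axis models and the tensor are frame equivariant", {
  set.seed(11)
  p <- default_params
  eta <- eta_bl(p)
  for (i in 1:50) {
    G <- random_traceless_sym(0.5) +
      (function(a) (a - t(a)) / 2)(matrix(rnorm(9, sd = 0.5), 3, 3))
    u <- rnorm(3, sd = 0.02)
    R <- random_rotation()
    sp <- stress_spectrum(viscous_stress(rate_of_deformation(G), eta), eta)
    spR <- stress_spectrum(viscous_stress(rate_of_deformation(R %*% G %*% t(R)), eta), eta)
    expect_equal(spR$tau_max, sp$tau_max, tolerance = 1e-10)
    ev <- eigenvector_axis(sp, u)$e_alpha
    evR <- eigenvector_axis(spR, as.numeric(R %*% u))$e_alpha
    expect_lt(angle_deg(as.numeric(R %*% ev), evR), 1e-8 * 180 / pi)
    vv <- lamb_axis(u, vorticity(G))$e_alpha
    vvR <- lamb_axis(as.numeric(R %*% u), vorticity(R %*% G %*% t(R)))$e_alpha
    expect_lt(angle_deg(as.numeric(R %*% vv), vvR), 1e-8 * 180 / pi)
    S <- assemble_tensor(ev, 0.4, 0.6)
    SR <- assemble_tensor(evR, 0.4, 0.6)
    expect_equal(SR, R %*% S %*% t(R), tolerance = 1e-8)
  }
})

test_that("the compiled batch kernel agrees with the single-point R path", {
  set.seed(23)
  p <- default_params
  eta <- eta_bl(p)
  n <- 60
  grads <- matrix(rnorm(9 * n, sd = 0.5), n, 9)
  # make each gradient traceless (incompressible)
  tr <- (grads[, 1] + grads[, 5] + grads[, 9]) / 3
  grads[, 1] <- grads[, 1] - tr; grads[, 5] <- grads[, 5] - tr
  grads[, 9] <- grads[, 9] - tr
  vels <- matrix(rnorm(3 * n, sd = 0.02), n, 3)
  ker <- hemocond:::stress_axes_batch(grads, vels, eta, 1e-12, 1e-8, 1e-9, 1e-30)
  for (i in seq_len(n)) {
    G <- matrix(grads[i, ], 3, 3, byrow = TRUE)
    u <- vels[i, ]
    sp <- stress_spectrum(viscous_stress(rate_of_deformation(G), eta), eta)
    expect_equal(unname(ker[i, "tau_max"]), sp$tau_max, tolerance = 1e-12)
    expect_equal(unname(ker[i, "gamma_dot_max"]), sp$gamma_dot_max, tolerance = 1e-12)
    ev <- eigenvector_axis(sp, u)$e_alpha
    expect_lt(angle_deg(ker[i, c("ev_x", "ev_y", "ev_z")], ev), 1e-8)
    vv <- lamb_axis(u, vorticity(G))$e_alpha
    expect_lt(angle_deg(ker[i, c("vv_x", "vv_y", "vv_z")], vv), 1e-10)
    expect_equal(unname(ker[i, "omega_x"]), vorticity(G)[1], tolerance = 1e-12)
  }
})
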