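# Scalar Maxwell-Fricke physics: shape factors, deformation, alignment and
# the principal conductivities. Reference values frozen from a
# high-precision (mpmath, 30 digits) evaluation of the same closed forms.

test_that("shape angle is the arccos of the aspect ratio with hard domain edges", {
  expect_equal(shape_angle(1), 0)
  expect_equal(shape_angle(0), pi / 2)
  expect_equal(shape_angle(0.38), 1.18100003032063606, tolerance = 1e-12)
  expect_error(shape_angle(1.2), "oblate")
  expect_error(shape_angle(-0.1), "oblate")
})

test_that("shape factor matches high-precision values and hits the sphere limit", {
  expect_equal(shape_factor(0.38), 0.398287363360206285, tolerance = 1e-12)
  expect_equal(shape_factor(0.3597), 0.384001157326479948, tolerance = 1e-12)
  # removable singularity at the sphere handled by the series limit
  expect_identical(shape_factor(1), 2 / 3)
  expect_equal(shape_factor(1 - 1e-9), 2 / 3, tolerance = 1e-9)
  # strictly increasing in lambda, range (0, 2/3]
  lam <- seq(0.01, 0.999, length.out = 100)
  M <- shape_factor(lam)
  expect_true(all(diff(M) > 0))
  expect_true(all(M > 0 & M <= 2 / 3))
})

test_that("orientation factors obey the sphere identity and the ordering C_a > 3/2 > C_b", {
  iso <- orientation_factors(2 / 3)
  expect_equal(iso$C_a, 1.5)
  expect_equal(iso$C_b, 1.5)
  of <- orientation_factors(0.38387)
  expect_equal(of$C_a, 2.605048584156095, tolerance = 1e-12)
  expect_equal(of$C_b, 1.237524209067340, tolerance = 1e-12)
  of2 <- orientation_factors(0.39826)
  expect_equal(of2$C_a, 2.510922512931251, tolerance = 1e-12)
  expect_equal(of2$C_b, 1.248642101714386, tolerance = 1e-12)
  lam <- seq(0.05, 0.95, length.out = 50)
  of <- orientation_factors(shape_factor(lam))
  expect_true(all(of$C_a > 1.5 & of$C_b < 1.5 & of$C_b >= 1))
  expect_error(orientation_factors(0), "\\(0, 2/3\\]")
})

test_that("random orientation factor is the axis average and sits between C_b and C_a", {
  expect_equal(random_orientation_factor(1.5, 1.5), 1.5)
  expect_equal(random_orientation_factor(2.6051, 1.2375), (2.6051 + 2 * 1.2375) / 3)
  lam <- seq(0.05, 0.95, length.out = 50)
  of <- orientation_factors(shape_factor(lam))
  cr <- random_orientation_factor(of$C_a, of$C_b)
  expect_true(all(cr >= of$C_b & cr <= of$C_a))
})

test_that("deformed aspect ratio starts at lambda and decreases with stress", {
  p <- default_params
  expect_equal(deformed_aspect_ratio(p, 0), p$lambda)
  # tau_max = 2 * eta_bl * 1.9 with eta_bl = 1060 * 4.59e-5
  expect_equal(deformed_aspect_ratio(p, 0.1848852), 0.359679082825999514,
               tolerance = 1e-12)
  tau <- seq(0, 5, length.out = 100)
  ld <- deformed_aspect_ratio(p, tau)
  expect_true(all(diff(ld) < 0))
  expect_lt(deformed_aspect_ratio(p, 1e9), 1e-12)
  expect_error(deformed_aspect_ratio(p, -0.1), "non-negative")
})

test_that("aligned fraction reproduces the 20%/80% boundary shear rates and is invertible", {
  expect_equal(aligned_fraction(0, 1), 0)
  expect_equal(aligned_fraction(1, 1), 0.5)
  expect_equal(aligned_fraction(0.0625, 1), 0.20)
  expect_equal(aligned_fraction(16, 1), 0.80)
  g <- seq(0, 100, length.out = 100)
  f <- aligned_fraction(g, 1)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
  # closed-form inverse round-trips
  expect_equal(alignment_shear_rate(0.20, 1), 0.0625)
  expect_equal(alignment_shear_rate(0.80, 1), 16)
  fs <- seq(0.01, 0.95, length.out = 20)
  expect_equal(aligned_fraction(alignment_shear_rate(fs, 2), 2), fs, tolerance = 1e-12)
  expect_error(aligned_fraction(-1, 1), "non-negative")
})

test_that("shear-rate classification tracks the alignment law, not fixed numbers", {
  expect_equal(as.character(classify_shear_rate(c(0.01, 1, 20))),
               c("low", "intermediate", "high"))
  # boundaries move with k: 16 s^-1 is only 'intermediate' for k = 2
  expect_equal(as.character(classify_shear_rate(16, k = 2)), "intermediate")
  expect_equal(as.character(classify_shear_rate(4 * 16, k = 2)), "high")
})

test_that("orientation-factor interpolation hits both ends and the mixed value", {
  ends <- interpolate_orientation_factors(2.6, 1.2, 1.7, c(0, 1))
  expect_equal(ends$C_alpha, c(1.7, 2.6))
  expect_equal(ends$C_beta, c(1.7, 1.2))
  mid <- interpolate_orientation_factors(2.6051, 1.2375, 1.6934, 0.57955)
  expect_equal(mid$C_alpha, 2.221775735, tolerance = 1e-9)
  expect_equal(mid$C_beta, 1.429183155, tolerance = 1e-9)
})

test_that("suspension conductivity is bounded by plasma and decreasing in C and H", {
  p <- default_params
  p0 <- blood_params(hematocrit = 0)
  expect_equal(conductivity_from_factor(c(1, 1.5, 2.6), p0),
               rep(p0$sigma_pl, 3))
  expect_equal(conductivity_from_factor(2.2217, p), 0.461360270750727,
               tolerance = 1e-12)
  expect_equal(conductivity_from_factor(1.6694, p), 0.549480107283109,
               tolerance = 1e-12)
  C <- seq(1, 3, length.out = 100)
  s <- conductivity_from_factor(C, p)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= p$sigma_pl))
  H <- seq(0, 0.9, length.out = 100)
  sH <- vapply(H, function(h) conductivity_from_factor(2, blood_params(hematocrit = h)),
               numeric(1))
  expect_true(all(diff(sH) < 0))
  expect_error(blood_params(hematocrit = 1), "\\[0, 1\\)")
})

test_that("rigid sphere limit recovers Maxwell's suspension conductivity at any shear", {
  # mu -> infinity keeps the near-spherical particle undeformed
  p <- blood_params(lambda = 1 - 1e-9, a = 4e-6 * (1 - 1e-9), b = 4e-6, mu = 1e12)
  pc <- principal_conductivities(c(0, 1.9, 50), p)
  maxwell <- maxwell_sphere_conductivity(p)
  expect_equal(maxwell, 1.3 * 0.55 / (1 + 0.45 / 2))
  expect_equal(pc$sigma_alpha, rep(maxwell, 3), tolerance = 1e-9)
  expect_equal(pc$sigma_beta, rep(maxwell, 3), tolerance = 1e-9)
})

test_that("shear state derives the missing member and rejects inconsistent pairs", {
  p <- default_params
  eta <- eta_bl(p)
  expect_equal(eta, 1060 * 4.59e-5)
  s1 <- shear_state(p, gamma_dot_max = 1.9)
  expect_equal(s1$tau_max, 2 * eta * 1.9)
  s2 <- shear_state(p, tau_max = s1$tau_max)
  expect_equal(s2$gamma_dot_max, 1.9)
  expect_silent(shear_state(p, tau_max = s1$tau_max, gamma_dot_max = 1.9))
  expect_error(shear_state(p, tau_max = s1$tau_max, gamma_dot_max = 2.1),
               "inconsistent")
})

test_that("the full chain at 1.9 1/s reproduces every frozen intermediate", {
  ch <- fricke_chain(1.9, default_params)
  expect_equal(ch$tau_max, 0.1848852, tolerance = 1e-12)
  expect_equal(ch$lambda_d, 0.359679082825999514, tolerance = 1e-10)
  expect_equal(ch$M, 0.383986155132958629, tolerance = 1e-10)
  expect_equal(ch$C_a, 2.604260561565667, tolerance = 1e-10)
  expect_equal(ch$C_b, 1.237613159288590, tolerance = 1e-10)
  expect_equal(ch$C_r, 1.693162293380949, tolerance = 1e-10)
  expect_equal(ch$f, 0.579550138656642, tolerance = 1e-10)
  expect_equal(ch$C_alpha, 2.221189421037228, tolerance = 1e-10)
  expect_equal(ch$C_beta, 1.429148729552809, tolerance = 1e-10)
  expect_equal(ch$sigma_alpha, 0.461428679896338, tolerance = 1e-10)
  expect_equal(ch$sigma_beta, 0.599270685916343, tolerance = 1e-10)
  expect_equal(ch$lambda_sigma, 0.769983733128493, tolerance = 1e-10)
  expect_equal(ch$eta_aniso, 0.083038851138566, tolerance = 1e-10)
})

test_that("stationary blood is isotropic at the random-orientation conductivity", {
  ch <- fricke_chain(0, default_params)
  expect_equal(ch$sigma_alpha, ch$sigma_beta)
  expect_equal(ch$sigma_alpha, 0.549487906476357, tolerance = 1e-10)
  expect_equal(ch$C_r, 1.669358957567136, tolerance = 1e-10)
  expect_equal(ch$f, 0)
  expect_equal(ch$eta_aniso, 0)
})

test_that("conductivity ratio decreases monotonically with shear rate", {
  g <- seq(0, 60, length.out = 200)
  ch <- fricke_chain(g, default_params)
  expect_true(all(diff(ch$lambda_sigma) < 0))
  expect_true(all(ch$sigma_alpha <= ch$sigma_beta))
  expect_true(all(ch$sigma_alpha > 0 & ch$sigma_beta <= default_params$sigma_pl))
})

test_that("fully aligned conductivities are the f = 1 limit of the chain", {
  p <- default_params
  tau <- c(0.05, 0.5, 2)
  al <- aligned_conductivities(p, tau)
  # very high shear rate at the same tau_max is approximated by a chain with
  # the deformation evaluated at tau and alignment at a huge shear rate
  lam_d <- deformed_aspect_ratio(p, tau)
  of <- orientation_factors(shape_factor(lam_d))
  expect_equal(al$sigma_a, conductivity_from_factor(of$C_a, p))
  expect_equal(al$sigma_b, conductivity_from_factor(of$C_b, p))
  expect_true(all(al$sigma_a < al$sigma_b))
})
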