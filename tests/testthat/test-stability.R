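test_that("dispersion relation has the required structure", {
  mp <- macro_preset("fig8", r_I = 0.14)
  expect_equal(dispersion(0, mp), 0 + 0i)
  # gamma = 0: pure self-repulsion damping at rate -(rho0/zeta) mu k^2
  mp0 <- macro_params(c1 = 1, mu = 6.7e-3, zeta = 8, gamma = 0, phi = mp$phi)
  k <- c(1, 5, 20)
  expect_equal(Re(dispersion(k, mp0)), -1 / 8 * 6.7e-3 * k^2)
  expect_equal(Im(dispersion(k, mp0)), -k)
  # delta = 0 order-gamma rate: independently coded reference formula
  ks <- 2 * pi * (1:10)
  ref <- 1 / mp$zeta * ks^2 *
    (mp$gamma / mp$eta * (ks * kernel_fourier(mp$phi, ks))^2 - mp$mu)
  expect_equal(Re(dispersion(ks, mp, gamma2_denominator = FALSE)), ref,
               tolerance = 1e-14)
  # reality symmetry: Re even, Im odd
  kk <- seq(-60, 60, by = 1.7)
  a <- dispersion(kk, mp)
  ar <- dispersion(-kk, mp)
  expect_equal(Re(a), Re(ar))
  expect_equal(Im(a), -Im(ar))
})

test_that("the memory-term denominator never flips the stability verdict", {
  set.seed(14)
  for (rep in 1:20) {
    mp <- macro_params(c1 = 1, mu = 10^stats::runif(1, -4, -1.5), zeta = 8,
                       gamma = 10^stats::runif(1, -3, -1.5),
                       delta = sample(c(0, 1e-3), 1),
                       phi = kernel_spec("quadratic_compact",
                                         stats::runif(1, 0.05, 0.5),
                                         stats::runif(1, 0.05, 0.3)))
    k <- 2 * pi * (1:40)
    s1 <- sign(Re(dispersion(k, mp)))
    s2 <- sign(Re(dispersion(k, mp, gamma2_denominator = FALSE)))
    expect_identical(s1, s2)
    # denominator positive
    D <- 1 + mp$gamma^2 / (mp$eta * mp$zeta) * k^2 *
      kernel_fourier(mp$phi, k)^2
    expect_true(all(D > 0))
  }
})

test_that("high wavenumbers are damped whenever self-repulsion is present", {
  mp <- macro_preset("fig8", r_I = 0.14)
  k_hi <- 2 * pi * seq(200, 400, by = 7)
  expect_true(all(Re(dispersion(k_hi, mp)) < 0))
})

test_that("stability criterion: sufficient condition, noise stabilisation, margins", {
  # large mu: stable on both mode sets
  stab <- macro_params(c1 = 1, mu = 0.5, zeta = 8, gamma = 2e-3,
                       phi = kernel_spec("quadratic_compact", 0.17, 0.14))
  expect_true(stability_criterion(stab, "torus")$stable)
  expect_true(stability_criterion(stab, "real")$stable)
  # sufficient condition (6C/(pi r_I))^2 < mu eta / gamma on the real line
  for (C in c(0.05, 0.17)) for (r_I in c(0.1, 0.2)) {
    mu <- 6.7e-3; gamma <- 2e-3
    mp <- macro_params(c1 = 1, mu = mu, zeta = 8, gamma = gamma,
                       phi = kernel_spec("quadratic_compact", C, r_I))
    cr <- stability_criterion(mp, "real")
    sufficient <- (6 * C / (pi * r_I))^2 < mu / gamma
    if (sufficient) expect_true(cr$stable)
    # the real-line maximiser sits at k = pi / r_I
    expect_equal(cr$k_max * r_I / pi, 1, tolerance = 1e-4)
    # torus criterion is never stricter than the real-line one
    expect_lte(stability_criterion(mp, "torus")$lhs, cr$lhs + 1e-12)
  }
  # obstacle noise never destabilises a noiseless-stable system
  set.seed(5)
  for (rep in 1:10) {
    C <- stats::runif(1, 0.02, 0.4); r_I <- stats::runif(1, 0.05, 0.3)
    mu <- 10^stats::runif(1, -4, -1)
    mp0 <- macro_params(c1 = 1, mu = mu, zeta = 8, gamma = 2e-3, delta = 0,
                        phi = kernel_spec("quadratic_compact", C, r_I))
    mpd <- macro_params(c1 = 1, mu = mu, zeta = 8, gamma = 2e-3,
                        delta = 10^stats::runif(1, -4, -2),
                        phi = kernel_spec("quadratic_compact", C, r_I))
    expect_lte(stability_criterion(mpd, "torus")$lhs,
               stability_criterion(mp0, "torus")$lhs + 1e-12)
  }
})

test_that("pattern-size prediction scans integer modes and flags stable regimes", {
  mp <- macro_preset("fig8", r_I = 0.14)
  pred <- predicted_pattern_size(mp)
  expect_false(pred$stable)
  expect_equal(pred$P, 1 / pred$l_max)
  # small mu (the pattern-scan family): the dominant mode tracks the kernel
  # gain maximiser k = pi/r_I, i.e. l ~ 1/(2 r_I). (With mu exactly zero the
  # argmax of Re alpha = const * k^4 hat phi_k^2 moves out to r_I k ~ 4.49,
  # the first minimum of sin(u)/u; finite self-repulsion damps that lobe.)
  for (r_I in c(0.1, 0.14, 0.16)) {
    mp0 <- macro_params(c1 = 1, mu = 6.7e-3, zeta = 8, gamma = 2e-3,
                        phi = kernel_spec("quadratic_compact", 0.17, r_I))
    pred0 <- predicted_pattern_size(mp0)
    expect_lte(abs(pred0$l_max - 1 / (2 * r_I)), 1)
  }
  # doubling the mode truncation changes nothing
  pred2 <- predicted_pattern_size(mp, l_cut = 2 * length(pred$l))
  expect_identical(pred$l_max, pred2$l_max)
  # stable bundle: no pattern predicted
  stab <- macro_params(c1 = 1, mu = 0.5, zeta = 8, gamma = 2e-3, phi = mp$phi)
  ps <- predicted_pattern_size(stab)
  expect_true(ps$stable)
  expect_true(is.na(ps$P))
})

test_that("pure self-repulsion decays at the heat-equation rate in simulation", {
  mp0 <- macro_params(c1 = 1, mu = 6.7e-3, zeta = 8, gamma = 0,
                      phi = kernel_spec("quadratic_compact", 0.17, 0.14))
  m <- simulate_linearized(3, 1e-6, mp0, T = 2)
  k <- 2 * pi * 3
  expect_equal(m$growth_rate, -1 / 8 * 6.7e-3 * k^2, tolerance = 1e-4)
  expect_equal(m$phase_speed, 1, tolerance = 1e-4)
})
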