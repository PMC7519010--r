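phi_ref <- kernel_spec("quadratic_compact", 0.25, 0.18)
grid_x <- function(n) (seq_len(n) - 1) / n

test_that("torus convolution reproduces single-mode multiplication and masses", {
  n <- 256; x <- grid_x(n)
  # constant field -> constant times kernel mass
  out <- convolve_field(field1d(rep(2, n)), phi_ref)
  expect_equal(out$values, rep(2 * kernel_mass(phi_ref), n))
  # single Fourier mode -> hat phi_k times the mode
  for (l in c(1, 5, 17)) {
    g <- field1d(cos(2 * pi * l * x))
    out <- convolve_field(g, phi_ref)
    expect_equal(out$values, kernel_fourier(phi_ref, 2 * pi * l) * g$values,
                 tolerance = 1e-12)
  }
  # zero-variance mollifier is the identity
  g <- field1d(1 + 0.3 * sin(2 * pi * 3 * x))
  expect_identical(convolve_field(g, mollifier(0))$values, g$values)
  # mollifier mass preservation
  out <- convolve_field(g, mollifier(1e-3))
  expect_equal(mean(out$values), mean(g$values), tolerance = 1e-14)
  expect_error(convolve_field(g, kernel_spec("quadratic_compact", 1, 0.6)),
               "0.5")
})

test_that("leading-order obstacle density matches the Fourier closed form", {
  n <- 256; x <- grid_x(n)
  gamma <- 2e-3; eta <- 1
  # constant SPP density and gamma = 0 both give rho_f identically 1
  expect_equal(rho_f_order1(field1d(rep(1.7, n)), gamma, eta, phi_ref)$values,
               rep(1, n))
  g <- field1d(1 + 0.2 * cos(2 * pi * 3 * x))
  expect_equal(rho_f_order1(g, 0, eta, phi_ref)$values, rep(1, n))
  # single mode: 1 - (gamma/eta) k^2 hat phi_k eps cos(kx)
  for (l in c(2, 6)) {
    eps <- 0.1; k <- 2 * pi * l
    g <- field1d(1 + eps * cos(k * x))
    expected <- 1 - gamma / eta * k^2 * kernel_fourier(phi_ref, k) * eps *
      cos(k * x)
    expect_equal(rho_f_order1(g, gamma, eta, phi_ref)$values, expected,
                 tolerance = 1e-12)
  }
})

test_that("noise closure: Fourier factor, delta->0 convergence at rate O(delta)", {
  n <- 256; x <- grid_x(n)
  gamma <- 2e-3; eta <- 1; delta <- 1e-3
  expect_equal(rho_f_noise(field1d(rep(1, n)), gamma, eta, delta,
                           phi_ref)$values, rep(1, n))
  # single mode: (1 - e^{-delta k^2})/delta replaces k^2
  l <- 4; k <- 2 * pi * l; eps <- 0.2
  g <- field1d(1 + eps * cos(k * x))
  fac <- (1 - exp(-delta * k^2)) / delta
  expected <- 1 - gamma / eta * fac * kernel_fourier(phi_ref, k) * eps *
    cos(k * x)
  expect_equal(rho_f_noise(g, gamma, eta, delta, phi_ref)$values, expected,
               tolerance = 1e-12)
  # measured convergence rate on the asymptotic window delta k^2 << 1
  g1 <- field1d(1 + 0.3 * cos(2 * pi * x))
  r1 <- rho_f_order1(g1, gamma, eta, phi_ref)$values
  ds <- 10^seq(-3, -6)
  errs <- vapply(ds, function(d)
    max(abs(rho_f_noise(g1, gamma, eta, d, phi_ref)$values - r1)),
    numeric(1))
  slope <- unname(coef(stats::lm(log(errs) ~ log(ds)))[2])
  expect_equal(slope, 1, tolerance = 0.05)
  expect_error(rho_f_noise(g1, gamma, eta, 0, phi_ref), "order1")
})

test_that("memory term: steady fields reduce to leading order, travelling waves shift minima backwards", {
  n <- 512; x <- grid_x(n)
  gamma <- 2e-3; eta <- 1
  g <- field1d(1 + 0.2 * cos(2 * pi * 3 * x))
  zero <- field1d(rep(0, n))
  expect_equal(rho_f_order2(g, zero, gamma, eta, 0, phi_ref)$values,
               rho_f_order1(g, gamma, eta, phi_ref)$values)
  # rightward wave rho(x - ct): dt rho = -c dx rho
  c_w <- 1
  dgdt <- field1d(-c_w * spobs:::spectral_deriv(g$values, 1L))
  r1 <- rho_f_order1(g, gamma, eta, phi_ref)
  r2 <- rho_f_order2(g, dgdt, gamma, eta, 0, phi_ref)
  # Fourier oracle for the added term: +(gamma^2/eta) c k^3 hat phi_k eps sin(kx)
  k <- 2 * pi * 3
  extra <- gamma^2 / eta * c_w * k^3 * kernel_fourier(phi_ref, k) * 0.2 *
    sin(k * x)
  expect_equal(r2$values - r1$values, extra, tolerance = 1e-10)
  # minima move backwards (to smaller x) relative to the SPP direction
  shift <- x[which.min(r2$values)] - x[which.min(r1$values)]
  shift <- shift - round(shift)
  expect_lt(shift, 0)
  expect_gt(shift, -0.05)
})

test_that("all closures leave the spatial mean at exactly 1 and are linear", {
  n <- 128
  set.seed(7)
  v <- 1 + 0.2 * convolve_field(field1d(stats::rnorm(n)), mollifier(1e-3))$values
  g <- field1d(v)
  gamma <- 2e-3; eta <- 1
  suppressWarnings({
    for (f in list(rho_f_order1(g, gamma, eta, phi_ref),
                   rho_f_noise(g, gamma, eta, 1e-4, phi_ref),
                   rho_f_order2(g, g, gamma, eta, 0, phi_ref)))
      expect_equal(mean(f$values), 1, tolerance = 1e-13)
  })
  # linearity by superposition of the deviation from 1
  g2 <- field1d(1 + 0.1 * sin(2 * pi * 5 * grid_x(n)))
  gs <- field1d(g$values + g2$values - 1)
  dev <- function(f) f$values - 1
  expect_equal(dev(rho_f_order1(gs, gamma, eta, phi_ref)),
               dev(rho_f_order1(g, gamma, eta, phi_ref)) +
                 dev(rho_f_order1(g2, gamma, eta, phi_ref)),
               tolerance = 1e-12)
})

test_that("negative obstacle density warns and is flagged, not clipped", {
  n <- 256
  g <- field1d(1 + 5 * cos(2 * pi * 4 * grid_x(n)))
  expect_warning(f <- rho_f_order1(g, 0.05, 1, phi_ref), "validity")
  expect_false(attr(f, "valid"))
  expect_lt(min(f$values), 0)
})

test_that("volume-deformation term: zero on 1D-structured fields, Gaussian oracle", {
  nx <- 64; xs <- grid_x(nx)
  # constant-in-y field
  v <- matrix(1 + 0.5 * cos(2 * pi * 2 * xs), nx, nx)
  expect_lt(max(abs(nonlinear_term(field2d(v))$values)), 1e-10)
  expect_equal(nonlinear_term(field2d(matrix(3, 32, 32)))$values,
               matrix(0, 32, 32))
  # radially symmetric Gaussian bump vs analytic derivatives
  s2 <- 0.004
  g2 <- outer(xs, xs, function(a, b) exp(-((a - 0.5)^2 + (b - 0.5)^2) / (2 * s2)))
  ana <- outer(xs, xs, function(a, b) {
    da <- a - 0.5; db <- b - 0.5
    g <- exp(-(da^2 + db^2) / (2 * s2))
    (g * (da^2 / s2^2 - 1 / s2)) * (g * (db^2 / s2^2 - 1 / s2)) -
      (g * da * db / s2^2)^2
  })
  N <- nonlinear_term(field2d(g2))
  expect_equal(N$values, ana, tolerance = 1e-10)
})

test_that("anchor-map Jacobian density: 1D equals leading order, 2D expands as 1 + a*Lap + a^2*N", {
  n <- 128; x <- grid_x(n)
  gamma <- 2e-3; eta <- 1
  g <- field1d(1 + 0.2 * cos(2 * pi * 3 * x))
  gb <- convolve_field(g, phi_ref)
  expect_equal(jacobian_det_density(gb, gamma, eta)$values,
               rho_f_order1(g, gamma, eta, phi_ref)$values, tolerance = 1e-12)
  expect_equal(jacobian_det_density(gb, 0, eta)$values, rep(1, n))
  # 2D expansion identity
  nx <- 64; xs <- grid_x(nx)
  v <- outer(xs, xs, function(a, b) exp(-((a - 0.5)^2 + (b - 0.5)^2) / 0.01))
  a <- gamma / eta
  H <- spobs:::spectral_hessian2d(v)
  expected <- 1 + a * (H$xx + H$yy) + a^2 * (H$xx * H$yy - H$xy^2)
  expect_equal(jacobian_det_density(field2d(v), gamma, eta)$values, expected,
               tolerance = 1e-14)
})
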