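phi1 <- kernel_spec("quadratic_compact", 0.25, 0.18)
psi1 <- kernel_spec("quadratic_compact", 5e-4, 0.02)

params_1d <- function(...) ibm_params(N = 4, M = 6, kappa = 500, zeta = 8,
                                      phi = phi1, psi = psi1,
                                      dimension = 1L, ...)

test_that("initial states place obstacles on their anchors, reproducibly", {
  p <- params_1d()
  st <- ibm_init(p, "lattice", seed = 3)
  expect_equal(st$X[, 1], c(0, 0.25, 0.5, 0.75))
  expect_identical(st$X, st$Y)
  st2 <- ibm_init(p, "lattice", seed = 3)
  expect_identical(st, st2)
  stu <- ibm_init(p, "uniform_random", seed = 8)
  expect_identical(stu$X, stu$Y)
  expect_true(all(stu$Z >= 0 & stu$Z < 1))
  expect_equal(max(obstacle_displacement(stu)), 0)
  p2 <- ibm_params(N = 9, M = 5, kappa = 10, zeta = 1, nu = 2, r_A = 0.1,
                   dimension = 2L)
  st3 <- ibm_init(p2, "lattice", seed = 1)
  expect_equal(nrow(st3$X), 9)
  expect_true(all(st3$theta >= 0 & st3$theta < 2 * pi))
})

test_that("mean direction equals the brute-force double loop and handles symmetry", {
  p <- ibm_preset("moving_clusters", N = 10, M = 10)
  st <- ibm_init(p, seed = 5)
  md <- ibm_mean_direction(st, p, method = "brute")
  J <- brute_mean_flux_r(st$Z, st$theta, p$r_A)
  nrm <- sqrt(rowSums(J^2))
  expect_equal(md$alpha_bar[md$defined, ], (J / nrm)[md$defined, ],
               tolerance = 1e-12)
  # unanimity
  st$theta <- rep(1.1, 10)
  md <- ibm_mean_direction(st, p)
  expect_equal(md$alpha_bar,
               matrix(c(cos(1.1), sin(1.1)), 10, 2, byrow = TRUE))
  # two symmetric headings average to the bisector
  Z <- matrix(c(0.5, 0.5, 0.52, 0.5), 2, 2, byrow = TRUE)
  st2 <- make_state(st$X, st$Y, Z, theta = c(pi / 4, -pi / 4))
  md2 <- ibm_mean_direction(st2, p)
  expect_equal(md2$alpha_bar, matrix(c(1, 0), 2, 2, byrow = TRUE))
})

test_that("cell-list forces equal brute force and the independent R oracle", {
  set.seed(99)
  for (rep in 1:10) {
    p <- ibm_params(N = 5, M = 5, kappa = 100, zeta = 2,
                    phi = kernel_spec("quadratic_compact", 1, 0.08),
                    psi = kernel_spec("quadratic_compact", 0.01, 0.05),
                    dimension = 1L)
    st <- ibm_init(p, "uniform_random", seed = rep)
    st$X <- wrap01(st$X + 0.02 * matrix(stats::runif(5, -1, 1), ncol = 1))
    fc <- ibm_forces(st, p, method = "cell")
    fb <- ibm_forces(st, p, method = "brute")
    fr <- brute_drift_r(st, p)
    expect_equal(fc$obstacle, fb$obstacle, tolerance = 1e-13)
    expect_equal(fc$spp, fb$spp, tolerance = 1e-13)
    expect_equal(fb$obstacle, fr$obstacle, tolerance = 1e-12)
    expect_equal(fb$spp, fr$spp, tolerance = 1e-12)
  }
  for (rep in 1:10) {
    p <- ibm_preset("moving_clusters", N = 8, M = 7)
    st <- ibm_init(p, seed = 100 + rep)
    st$X <- wrap01(st$X + 0.01 * matrix(stats::runif(16, -1, 1), ncol = 2))
    fc <- ibm_forces(st, p, method = "cell")
    fb <- ibm_forces(st, p, method = "brute")
    fr <- brute_drift_r(st, p)
    expect_equal(fc$obstacle, fb$obstacle, tolerance = 1e-13)
    expect_equal(fc$spp, fb$spp, tolerance = 1e-13)
    expect_equal(fb$obstacle, fr$obstacle, tolerance = 1e-12)
    expect_equal(fb$spp, fr$spp, tolerance = 1e-12)
  }
})

test_that("a lone SPP self-propels at unit speed; springs relax exponentially", {
  # free 1D self-propulsion
  p <- ibm_params(N = 1, M = 1, kappa = 10, zeta = 1, dimension = 1L,
                  dt = 1e-3)
  st <- make_state(matrix(0.2), matrix(0.2), matrix(0.1))
  run <- ibm_run(p, T = 0.25, save_every = 0.25, state = st)
  fin <- run$states[[length(run$states)]]
  expect_equal(fin$Z[1, 1], wrap01(0.1 + 0.25), tolerance = 1e-12)
  expect_equal(fin$X[1, 1], 0.2)   # obstacle untouched without interaction
  # spring relaxation |X - Y| = d0 exp(-kappa t / eta)
  p2 <- ibm_params(N = 1, M = 1, kappa = 10, zeta = 1, dimension = 1L,
                   dt = 2e-4)
  st2 <- make_state(matrix(0.55), matrix(0.5), matrix(0.9))
  run2 <- ibm_run(p2, T = 0.5, save_every = 0.5, state = st2)
  d <- obstacle_displacement(run2$states[[length(run2$states)]])
  expect_equal(d, 0.05 * exp(-10 * 0.5), tolerance = 0.03)
})

test_that("runs are deterministic given a seed and conserve counts and anchors", {
  p <- ibm_preset("moving_clusters", N = 16, M = 16)
  r1 <- ibm_run(p, T = 0.05, save_every = 0.05, seed = 7)
  r2 <- ibm_run(p, T = 0.05, save_every = 0.05, seed = 7)
  expect_identical(r1$states, r2$states)
  fin <- r1$states[[length(r1$states)]]
  expect_identical(fin$Y, r1$states[[1]]$Y)
  expect_equal(dim(fin$Z), c(16L, 2L))
  # T = 0 returns the initial state
  r0 <- ibm_run(p, T = 0, seed = 7)
  expect_length(r0$states, 1L)
})

test_that("without interactions and noise, obstacles never move and angles are frozen", {
  p <- ibm_params(N = 6, M = 4, kappa = 50, zeta = 1, nu = 3, r_A = 0.2,
                  d_s = 0, d_o = 0, dimension = 2L, dt = 1e-3)
  st <- ibm_init(p, seed = 2)
  st$theta <- rep(0.7, 4)           # unanimous heading: zero alignment drift
  for (i in 1:20) st <- ibm_step(st, p)
  expect_identical(st$X, st$Y)
  expect_equal(st$theta, rep(0.7, 4), tolerance = 1e-14)
})

test_that("the 1D mode never touches orientations and matches the step-by-step integrator", {
  p <- params_1d(dt = 1e-3)
  st0 <- ibm_init(p, "lattice", seed = 13)
  expect_null(st0$theta)
  stR <- st0
  for (i in 1:7) stR <- ibm_step(stR, p)
  runC <- ibm_run(p, T = 7e-3, save_every = 7e-3, seed = 13,
                  anchor_layout = "lattice")
  stC <- runC$states[[length(runC$states)]]
  expect_equal(stC$X, stR$X, tolerance = 1e-14)
  expect_equal(stC$Z, stR$Z, tolerance = 1e-14)
  expect_null(stC$theta)
})

test_that("neighbourhood density and direction variance behave as documented", {
  # all SPPs at one point
  Z <- matrix(0.3, 8, 2)
  st <- make_state(matrix(stats::runif(4), 2), matrix(stats::runif(4), 2), Z,
                   theta = rep(0, 8))
  expect_equal(neighborhood_density(st, 0.1), rep(1 / (pi * 0.1^2), 8))
  expect_error(neighborhood_density(st, 0.5), "0.5")
  # single SPP counts itself
  st1 <- make_state(st$X, st$Y, matrix(0.5, 1, 2), theta = 0)
  expect_equal(neighborhood_density(st1, 0.1), 1 / (pi * 0.1^2))
  # uniform particles: mean relative density near 1 (self-count bias small)
  set.seed(31)
  means <- vapply(1:10, function(s) {
    Z <- matrix(stats::runif(4000), ncol = 2)
    mean(neighborhood_density(make_state(st$X, st$Y, Z, theta = NULL), 0.2))
  }, numeric(1))
  expect_lt(abs(mean(means) - 1), 0.02)
  # direction variance: aligned -> 0, balanced -> 1
  expect_equal(direction_variance(make_state(st$X, st$Y, Z,
                                             rep(2.2, 8))), 0)
  grid_theta <- 2 * pi * (0:63) / 64
  expect_equal(direction_variance(make_state(st$X, st$Y,
                                             matrix(0.1, 64, 2), grid_theta)),
               1, tolerance = 1e-12)
})

test_that("parameter validation rejects invalid geometries", {
  expect_error(ibm_params(N = 2, M = 2, kappa = 1, zeta = 1,
                          phi = kernel_spec("quadratic_compact", 1, 0.6,
                                            dimension = 1L),
                          dimension = 1L),
               "minimum-image")
  expect_error(ibm_params(N = 2, M = 2, kappa = 1, zeta = 1, r_A = 0.7),
               "alignment")
})
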