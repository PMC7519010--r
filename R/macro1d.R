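# Time integration of the 1D nonlocal macroscopic SPP density equation
#   dt rho + c1 dx rho = (1/zeta) dx( mu rho dx rho + rho dx(phi * rho_f) )
# coupled to an asymptotic obstacle-density closure, in conservative flux
# form with spectral derivatives (exact mass conservation) and explicit RK4.

#' Macroscopic model parameters
#'
#' @param c1 transport speed of the aligned SPP phase (the simulations in
#'   this package use the nondimensional value 1).
#' @param mu SPP self-repulsion mass \eqn{\mu = \int\psi \ge 0}.
#' @param zeta SPP friction \eqn{\zeta > 0}.
#' @param eta obstacle friction \eqn{\eta > 0}.
#' @param gamma spring relaxation scale \eqn{\gamma = \eta/\kappa \ge 0}.
#' @param delta rescaled obstacle noise \eqn{\delta = d_o\gamma \ge 0}.
#' @param rho0 mean SPP density (>0).
#' @param phi SPP--obstacle interaction [kernel_spec()].
#' @param closure obstacle-density closure: `"order1"` (leading order,
#'   zero noise), `"order1_noise"` (leading order with noise blur,
#'   requires `delta > 0`), or `"order2"` (adds the memory term; the solver
#'   then uses a lagged finite-difference time derivative).
#' @param c2 transported orientation speed (stored for completeness; it does
#'   not enter the 1D density equation).
#' @param d orientational noise-to-alignment ratio \eqn{d = d_s/\nu}
#'   (informational).
#' @export
macro_params <- function(c1 = 1, mu, zeta, eta = 1, gamma, delta = 0,
                         rho0 = 1, phi,
                         closure = c("order1", "order1_noise", "order2"),
                         c2 = NA_real_, d = NA_real_) {
  closure <- match.arg(closure)
  stopifnot(c1 > 0, mu >= 0, zeta > 0, eta > 0, gamma >= 0, delta >= 0,
            rho0 > 0, is_kernel_spec(phi), phi$dimension == 1L)
  if (closure == "order1_noise" && delta <= 0)
    stop("closure 'order1_noise' requires delta > 0")
  structure(list(c1 = c1, c2 = c2, d = d, mu = mu, zeta = zeta, eta = eta,
                 gamma = gamma, delta = delta, rho0 = rho0, phi = phi,
                 closure = closure),
            class = "macro_params")
}

#' @export
print.macro_params <- function(x, ...) {
  cat(sprintf(
    "<macro_params> c1=%g mu=%g zeta=%g eta=%g gamma=%g delta=%g rho0=%g closure=%s\n",
    x$c1, x$mu, x$zeta, x$eta, x$gamma, x$delta, x$rho0, x$closure))
  print(x$phi)
  invisible(x)
}

# deviation of rho_f from 1 in Fourier space, as a multiplier acting on
# fft(rho_g); vhat_dt is fft of the lagged d rho_g/dt (order2 closure)
rho_f_dev_hat <- function(vhat, vhat_dt, params, k) {
  phat <- kernel_fourier(params$phi, k)
  nf <- if (params$delta > 0 && params$closure != "order1")
    (1 - exp(-params$delta * k^2)) / params$delta else k^2
  dev <- -params$gamma / params$eta * nf * phat * vhat
  if (params$closure == "order2" && !is.null(vhat_dt))
    dev <- dev + params$gamma^2 / params$eta * k^2 * phat * vhat_dt
  dev
}

macro_rhs_values <- function(v, params, dvdt = NULL) {
  if (any(!is.finite(v))) stop("non-finite density encountered in macro_rhs")
  n <- length(v)
  k <- 2 * pi * fft_modes(n)
  nyq <- if (n %% 2 == 0) n / 2 + 1 else 0L
  ik <- 1i * k
  if (nyq > 0) ik[nyq] <- 0
  vhat <- stats::fft(v)
  vhat_dt <- if (!is.null(dvdt)) stats::fft(dvdt) else NULL
  dev <- rho_f_dev_hat(vhat, vhat_dt, params, k)
  phat <- kernel_fourier(params$phi, k)
  dx_rbf <- Re(stats::fft(ik * phat * dev, inverse = TRUE)) / n
  dx_rho <- Re(stats::fft(ik * vhat, inverse = TRUE)) / n
  flux <- params$c1 * v -
    (params$mu * v * dx_rho + v * dx_rbf) / params$zeta
  -Re(stats::fft(ik * stats::fft(flux), inverse = TRUE)) / n
}

#' Right-hand side of the 1D macroscopic density equation
#'
#' Flux-form evaluation of
#' \eqn{\partial_t\rho_g = -\partial_x\left[c_1\rho_g -
#' \frac{1}{\zeta}(\mu\rho_g\partial_x\rho_g +
#' \rho_g\partial_x\bar\rho_f)\right]} with
#' \eqn{\bar\rho_f = \phi*\rho_f} from the chosen closure and spectral
#' derivatives. A constant field is an exact steady state.
#'
#' @param rho_g SPP density, a [field1d()].
#' @param params a [macro_params()].
#' @param prev_rho_g previous snapshot (required for `closure = "order2"`).
#' @param dt_prev time separation of `prev_rho_g` from `rho_g`.
#' @return A [field1d()] holding \eqn{\partial_t\rho_g}.
#' @export
macro_rhs <- function(rho_g, params, prev_rho_g = NULL, dt_prev = NULL) {
  stopifnot(inherits(rho_g, "field1d"), inherits(params, "macro_params"))
  dvdt <- NULL
  if (params$closure == "order2") {
    if (is.null(prev_rho_g) || is.null(dt_prev))
      stop("closure 'order2' needs prev_rho_g and dt_prev for the time derivative")
    dvdt <- (rho_g$values - prev_rho_g$values) / dt_prev
  }
  field1d(macro_rhs_values(rho_g$values, params, dvdt), t = rho_g$t)
}

#' Gradient-flow form of the macroscopic density equation
#'
#' Evaluates the algebraically equivalent form
#' \eqn{\partial_t\rho_g + c_1\partial_x\rho_g = \frac{1}{\zeta}\partial_x
#' \left[\rho_g\partial_x\left(\mu\rho_g +
#' \frac{\gamma}{\eta}W*\rho_g\right)\right]} with the obstacle-induced
#' kernel \eqn{W = \phi'*\phi'} applied in Fourier space
#' (\eqn{\hat W_k = -k^2\hat\phi_k^2}). This is the transport-plus-gradient
#' flow of the energy computed by [interaction_energy()].
#'
#' @inheritParams macro_rhs
#' @export
gradient_flow_rhs <- function(rho_g, params) {
  stopifnot(inherits(rho_g, "field1d"), inherits(params, "macro_params"))
  v <- rho_g$values
  n <- length(v)
  k <- 2 * pi * fft_modes(n)
  nyq <- if (n %% 2 == 0) n / 2 + 1 else 0L
  ik <- 1i * k
  if (nyq > 0) ik[nyq] <- 0
  vhat <- stats::fft(v)
  What <- -k^2 * kernel_fourier(params$phi, k)^2
  Wconv <- Re(stats::fft(What * vhat, inverse = TRUE)) / n
  inner <- params$mu * v + params$gamma / params$eta * Wconv
  dx_inner <- Re(stats::fft(ik * stats::fft(inner), inverse = TRUE)) / n
  dx_rho <- Re(stats::fft(ik * vhat, inverse = TRUE)) / n
  div <- Re(stats::fft(ik * stats::fft(v * dx_inner), inverse = TRUE)) / n
  field1d(-params$c1 * dx_rho + div / params$zeta, t = rho_g$t)
}

#' Free energy of the gradient-flow structure
#'
#' \eqn{E[\rho] = \int\left[\frac{\mu}{2}\rho^2 +
#' \frac{\gamma}{2\eta}\rho\,(W*\rho)\right]dx}: internal energy of the SPP
#' self-repulsion plus the obstacle-mediated interaction energy. Along
#' solutions, in the frame moving with speed \eqn{c_1}, \eqn{E} is
#' non-increasing (dissipation \eqn{-\frac{1}{\zeta}\int\rho|\partial_x
#' \delta E/\delta\rho|^2}).
#'
#' @inheritParams macro_rhs
#' @export
interaction_energy <- function(rho_g, params) {
  v <- rho_g$values
  n <- length(v)
  k <- 2 * pi * fft_modes(n)
  What <- -k^2 * kernel_fourier(params$phi, k)^2
  Wconv <- Re(stats::fft(What * stats::fft(v), inverse = TRUE)) / n
  sum(params$mu / 2 * v^2 + params$gamma / (2 * params$eta) * v * Wconv) / n
}

# largest grid growth/oscillation rate: mu-diffusion + obstacle-induced
# anti-diffusion + advection; used for the adaptive RK4 step
macro_max_rate <- function(v, params, k) {
  phat2 <- kernel_fourier(params$phi, k)^2
  rmax <- max(abs(v), params$rho0)
  nf <- if (params$delta > 0 && params$closure != "order1")
    (1 - exp(-params$delta * k^2)) / params$delta else k^2
  kmax <- max(abs(k))
  (rmax / params$zeta) * (params$mu * kmax^2 +
                            params$gamma / params$eta * max(nf * phat2 * k^2)) +
    params$c1 * kmax
}

#' One explicit RK4 step of the macroscopic equation
#'
#' @inheritParams macro_rhs
#' @param dt time step. The caller is responsible for respecting the
#'   stability limit; [macro_run()] chooses the step adaptively.
#' @param prev_rho_g,dt_prev lagged snapshot for `closure = "order2"` (the
#'   time derivative is held fixed across the four stages).
#' @export
macro_step <- function(rho_g, params, dt, prev_rho_g = NULL, dt_prev = NULL) {
  stopifnot(inherits(rho_g, "field1d"), dt > 0)
  v <- rho_g$values
  dvdt <- if (params$closure == "order2") {
    if (is.null(prev_rho_g)) stop("closure 'order2' needs prev_rho_g")
    (v - prev_rho_g$values) / dt_prev
  } else NULL
  k1 <- macro_rhs_values(v, params, dvdt)
  k2 <- macro_rhs_values(v + dt / 2 * k1, params, dvdt)
  k3 <- macro_rhs_values(v + dt / 2 * k2, params, dvdt)
  k4 <- macro_rhs_values(v + dt * k3, params, dvdt)
  field1d(v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), t = rho_g$t + dt)
}

# mild exponential high-mode filter (removes only the top ~15% of modes to
# machine precision scale); DC untouched so mass is conserved exactly
spectral_filter <- function(v) {
  n <- length(v)
  m <- abs(fft_modes(n)) / floor(n / 2)
  Re(stats::fft(stats::fft(v) * exp(-36 * m^36), inverse = TRUE)) / n
}

#' Integrate the 1D macroscopic model
#'
#' Method-of-lines integration: spectral flux-form right-hand side, explicit
#' RK4 with a step chosen adaptively from the linear rate bound (diffusion,
#' obstacle-induced growth and advection), and a mild exponential high-mode
#' filter to control aliasing near steep cluster edges. Mass is conserved to
#' round-off. If the density undershoots below `-1e-8` the run is flagged
#' (`undershoot` attribute); spectral schemes can undershoot near vacuum.
#'
#' @param initial initial SPP density, a [field1d()].
#' @param params a [macro_params()].
#' @param T final time.
#' @param save_every snapshot cadence in time units (default: 10 snapshots).
#' @param cfl safety factor for the stability bound.
#' @param filter logical; apply the high-mode filter each step.
#' @param verbose print progress.
#' @return List with `fields` (snapshots, `field1d` with time stamps),
#'   `times`, `params`, and attributes `undershoot`/`min_density`.
#' @export
macro_run <- function(initial, params, T, save_every = NULL, cfl = 0.8,
                      filter = TRUE, verbose = FALSE) {
  stopifnot(inherits(initial, "field1d"), T >= 0)
  if (is.null(save_every)) save_every <- if (T > 0) T / 10 else 1
  n <- initial$n
  k <- 2 * pi * fft_modes(n)
  v <- initial$values
  t <- initial$t
  save_times <- if (T > 0) seq(initial$t, initial$t + T, by = save_every) else initial$t
  out <- vector("list", length(save_times))
  out[[1]] <- field1d(v, t = t)
  isave <- 2L
  prev <- NULL; dt_prev <- NULL
  min_rho <- min(v)
  t_end <- initial$t + T
  while (t < t_end - 1e-12) {
    dt <- cfl * 2.5 / macro_max_rate(v, params, k)
    t_next <- if (isave <= length(save_times)) save_times[isave] else t_end
    dt <- min(dt, t_next - t, t_end - t)
    dvdt <- if (params$closure == "order2" && !is.null(prev))
      (v - prev) / dt_prev else NULL
    k1 <- macro_rhs_values(v, params, dvdt)
    k2 <- macro_rhs_values(v + dt / 2 * k1, params, dvdt)
    k3 <- macro_rhs_values(v + dt / 2 * k2, params, dvdt)
    k4 <- macro_rhs_values(v + dt * k3, params, dvdt)
    prev <- v; dt_prev <- dt
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (filter) v <- spectral_filter(v)
    t <- t + dt
    min_rho <- min(min_rho, min(v))
    if (any(!is.finite(v)))
      stop(sprintf("macro_run: non-finite density at t = %.4g", t))
    if (isave <= length(save_times) && t >= save_times[isave] - 1e-12) {
      out[[isave]] <- field1d(v, t = t)
      if (verbose) message(sprintf("t = %.3f  (dt = %.2e, max rho = %.3f)",
                                   t, dt, max(v)))
      isave <- isave + 1L
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- list(fields = out, times = vapply(out, function(f) f$t, numeric(1)),
              params = params)
  attr(res, "undershoot") <- min_rho < -1e-8
  attr(res, "min_density") <- min_rho
  res
}

#' Perturbed-uniform initial condition
#'
#' Uniform density `rho0` with i.i.d. uniform noise of relative amplitude
#' `amplitude` per node, smoothed by one mollifier pass and recentred so the
#' mean is exactly `rho0`. Excites all resolved modes; used as the generic
#' pattern-formation initial condition.
#'
#' @param n grid size.
#' @param rho0 mean density.
#' @param amplitude relative perturbation amplitude.
#' @param smooth_delta variance of the smoothing mollifier.
#' @param seed RNG seed.
#' @export
perturbed_uniform_density <- function(n = 512, rho0 = 1, amplitude = 1e-2,
                                      smooth_delta = 1e-4, seed = 1) {
  set.seed(seed)
  noise <- stats::runif(n, -1, 1) * amplitude * rho0
  f <- convolve_field(field1d(rho0 + noise), mollifier(smooth_delta))
  field1d(f$values - mean(f$values) + rho0)
}

#' Central Gaussian-bump initial condition
#'
#' Wrapped Gaussian centred at `center`, normalised so the spatial mean is
#' `rho0`.
#'
#' @param n grid size.
#' @param rho0 mean density.
#' @param center bump location.
#' @param sd bump width (standard deviation).
#' @export
gaussian_bump_density <- function(n = 512, rho0 = 1, center = 0.5, sd = 0.05) {
  x <- (seq_len(n) - 1) / n
  d <- x - center
  d <- d - round(d)
  v <- exp(-d^2 / (2 * sd^2))
  field1d(v / mean(v) * rho0)
}
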