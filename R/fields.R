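# Periodic density fields on the unit torus and the asymptotic
# obstacle-density closures derived from a given SPP density.

#' Density field on a uniform periodic 1D grid
#'
#' @param values density values at the nodes `x = (0:(n-1))/n` of `[0, 1)`.
#' @param t time stamp.
#' @return An object of class `field1d`.
#' @export
field1d <- function(values, t = 0) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  n <- length(values)
  structure(list(values = as.numeric(values), n = n, dx = 1 / n,
                 x = (seq_len(n) - 1) / n, t = t),
            class = "field1d")
}

#' Density field on a uniform periodic 2D grid
#'
#' @param values matrix of density values on the tensor grid of `[0, 1)^2`.
#' @param t time stamp.
#' @export
field2d <- function(values, t = 0) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(list(values = values, nx = nrow(values), ny = ncol(values),
                 dx = 1 / nrow(values), dy = 1 / ncol(values), t = t),
            class = "field2d")
}

#' @export
print.field1d <- function(x, ...) {
  cat(sprintf("<field1d> n = %d, t = %g, mean = %.6g, range [%.4g, %.4g]\n",
              x$n, x$t, mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Spatial mean of a field
#' @param field a `field1d` or `field2d`.
#' @export
field_mean <- function(field) mean(field$values)

# integer FFT mode numbers in R's fft ordering
fft_modes <- function(n) {
  if (n %% 2 == 0) c(0:(n / 2 - 1), seq(-n / 2, -1)) else
    c(0:((n - 1) / 2), seq(-(n - 1) / 2, -1))
}

# spectral derivative of given order on [0,1) periodic; the Nyquist mode is
# zeroed for odd orders (it carries no sign information)
spectral_deriv <- function(v, order = 1L) {
  n <- length(v)
  k <- 2 * pi * fft_modes(n)
  mult <- (1i * k)^order
  if (order %% 2 == 1 && n %% 2 == 0) mult[n / 2 + 1] <- 0
  Re(stats::fft(stats::fft(v) * mult, inverse = TRUE)) / n
}

# apply a real even Fourier multiplier (given as a function of k)
apply_multiplier <- function(v, mult_fun) {
  n <- length(v)
  k <- 2 * pi * fft_modes(n)
  Re(stats::fft(stats::fft(v) * mult_fun(k), inverse = TRUE)) / n
}

#' Gaussian mollifier on the torus
#'
#' The wrapped Gaussian \eqn{M_\delta(z) \propto e^{-|z|^2/(2\delta)}} with
#' unit mass; wrapping preserves the mass exactly and its torus Fourier
#' coefficients are \eqn{e^{-\delta k^2 / 2}}.
#'
#' @param delta variance parameter \eqn{\delta \ge 0} (\eqn{\delta = 0} is
#'   the identity).
#' @param dimension 1 or 2.
#' @export
mollifier <- function(delta, dimension = 1L) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  structure(list(delta = delta, dimension = as.integer(dimension)),
            class = "mollifier")
}

#' Circular convolution of a field with a kernel or mollifier
#'
#' FFT-based convolution on the torus. The DC component is multiplied by the
#' kernel mass, so a constant field maps to `constant * mass` and mass is
#' preserved exactly for a unit-mass kernel.
#'
#' @param field a [field1d()].
#' @param kernel a [kernel_spec()] (effective support must fit in half the
#'   domain) or a [mollifier()].
#' @export
convolve_field <- function(field, kernel) {
  stopifnot(inherits(field, "field1d"))
  if (inherits(kernel, "mollifier")) {
    if (kernel$delta == 0) return(field)
    d <- kernel$delta
    out <- apply_multiplier(field$values, function(k) exp(-d * k^2 / 2))
  } else {
    stopifnot(is_kernel_spec(kernel), kernel$dimension == 1L)
    r_eff <- if (kernel$family == "quadratic_compact") kernel$range else
      10 * kernel$range
    if (r_eff >= 0.5)
      stop("kernel range >= 0.5: support does not fit on the unit torus")
    out <- apply_multiplier(field$values, function(k) kernel_fourier(kernel, k))
  }
  field1d(out, t = field$t)
}

rho_f_wrap <- function(values, t) {
  fld <- field1d(values, t = t)
  valid <- min(values) > 0
  if (!valid)
    warning(sprintf("obstacle density reaches %.3g < 0: outside the validity regime of the stiff-spring expansion",
                    min(values)), call. = FALSE)
  attr(fld, "valid") <- valid
  fld
}

#' Obstacle density, leading order in the spring relaxation scale
#'
#' \eqn{\rho_f = 1 + \frac{\gamma}{\eta}\partial_x^2 \bar\rho_g} with
#' \eqn{\bar\rho_g = \phi * \rho_g}: obstacles are depleted where the
#' smoothed SPP density is peaked (repulsive \eqn{\phi}) and enriched for an
#' attractive one. For \eqn{\gamma = 0} (infinitely stiff springs) the
#' obstacles stay at their anchors and \eqn{\rho_f \equiv 1}. A negative
#' result is returned as-is with a warning and a `valid = FALSE` attribute:
#' negativity flags the limit of validity of the expansion, not a numerical
#' error.
#'
#' @param rho_g SPP density, a [field1d()].
#' @param gamma spring relaxation scale \eqn{\gamma = \eta/\kappa \ge 0}.
#' @param eta obstacle friction \eqn{\eta > 0}.
#' @param phi SPP--obstacle [kernel_spec()].
#' @export
rho_f_order1 <- function(rho_g, gamma, eta, phi) {
  stopifnot(inherits(rho_g, "field1d"), gamma >= 0, eta > 0)
  rb <- convolve_field(rho_g, phi)
  rho_f_wrap(1 + gamma / eta * spectral_deriv(rb$values, 2L), rho_g$t)
}

#' Obstacle density at leading order with positional obstacle noise
#'
#' \eqn{\rho_f = 1 - \frac{\gamma}{\delta\eta}\left[\bar\rho_g -
#' M_{2\delta} * \bar\rho_g\right]}. In Fourier space the correction factor
#' \eqn{(1 - e^{-\delta k^2})/\delta} replaces \eqn{k^2}; as
#' \eqn{\delta \to 0} this converges to [rho_f_order1()] at rate
#' \eqn{O(\delta)}.
#'
#' @inheritParams rho_f_order1
#' @param delta rescaled obstacle noise \eqn{\delta = d_o \gamma > 0};
#'   for `delta = 0` use [rho_f_order1()].
#' @export
rho_f_noise <- function(rho_g, gamma, eta, delta, phi) {
  stopifnot(inherits(rho_g, "field1d"), gamma >= 0, eta > 0)
  if (delta <= 0)
    stop("delta must be > 0; use rho_f_order1() for the zero-noise limit")
  rb <- convolve_field(rho_g, phi)$values
  # [rho_bar - M_{2 delta} * rho_bar] has Fourier multiplier 1 - e^{-delta k^2}
  blur_diff <- apply_multiplier(rb, function(k) 1 - exp(-delta * k^2))
  rho_f_wrap(1 - gamma / (delta * eta) * blur_diff, rho_g$t)
}

#' Obstacle density including the order-\eqn{\gamma^2} memory term
#'
#' Adds \eqn{-\frac{\gamma^2}{\eta}\partial_t\partial_x^2\bar\rho_g} to the
#' order-\eqn{\gamma} (or noise-corrected) expression. The time derivative of
#' the SPP density must be supplied, typically a forward finite difference of
#' consecutive snapshots. The memory term shifts the obstacle-density minima
#' backwards relative to the SPP motion: obstacles remember where the SPPs
#' were.
#'
#' @inheritParams rho_f_order1
#' @param drho_g_dt time derivative of the SPP density, a [field1d()].
#' @param delta rescaled obstacle noise \eqn{\delta \ge 0}; 0 selects the
#'   noiseless leading term.
#' @export
rho_f_order2 <- function(rho_g, drho_g_dt, gamma, eta, delta = 0, phi) {
  stopifnot(inherits(drho_g_dt, "field1d"), drho_g_dt$n == rho_g$n)
  base <- if (delta > 0) rho_f_noise(rho_g, gamma, eta, delta, phi) else
    rho_f_order1(rho_g, gamma, eta, phi)
  dtb <- convolve_field(drho_g_dt, phi)$values
  rho_f_wrap(base$values - gamma^2 / eta * spectral_deriv(dtb, 2L), rho_g$t)
}

# 2D spectral second derivatives of a matrix field
spectral_hessian2d <- function(v) {
  nx <- nrow(v); ny <- ncol(v)
  kx <- 2 * pi * fft_modes(nx)
  ky <- 2 * pi * fft_modes(ny)
  vhat <- stats::fft(v)
  inv <- function(m) Re(stats::fft(m, inverse = TRUE)) / (nx * ny)
  KX2 <- matrix(kx^2, nx, ny)
  KY2 <- matrix(ky^2, nx, ny, byrow = TRUE)
  KXY <- outer(kx, ky)
  list(xx = inv(-KX2 * vhat), yy = inv(-KY2 * vhat), xy = inv(-KXY * vhat))
}

#' Quadratic volume-deformation term \eqn{\mathcal{N}(\bar\rho_g)}
#'
#' \eqn{\mathcal{N}(\bar\rho) = \frac12\left[(\Delta\bar\rho)^2 -
#' \mathbb{H}(\bar\rho):\mathbb{H}(\bar\rho)\right]}, which in 2D reduces to
#' the Hessian determinant
#' \eqn{\partial_{xx}\bar\rho\,\partial_{yy}\bar\rho -
#' (\partial_{xy}\bar\rho)^2}. It vanishes identically on fields with 1D
#' structure (constant along one axis).
#'
#' @param rho_bar smoothed density \eqn{\bar\rho_g}, a [field2d()].
#' @export
nonlinear_term <- function(rho_bar) {
  stopifnot(inherits(rho_bar, "field2d"))
  H <- spectral_hessian2d(rho_bar$values)
  field2d(H$xx * H$yy - H$xy^2, t = rho_bar$t)
}

#' Obstacle density as an anchor-map Jacobian determinant
#'
#' Computes \eqn{\det J_Y} for the anchor-estimate map
#' \eqn{Y(x,t) = x + \frac{\gamma}{\eta}\nabla_x\bar\rho_g}: the deformation
#' of an obstacle volume element under the SPP forcing. In 1D this is
#' \eqn{1 + \frac{\gamma}{\eta}\partial_x^2\bar\rho_g}, identical to the
#' leading-order density; in 2D the expansion to order \eqn{\gamma^2} is
#' \eqn{1 + \frac{\gamma}{\eta}\Delta\bar\rho_g +
#' \frac{\gamma^2}{\eta^2}\mathcal{N}(\bar\rho_g)}.
#'
#' @param rho_bar smoothed density \eqn{\bar\rho_g}, a [field1d()] or
#'   [field2d()].
#' @inheritParams rho_f_order1
#' @export
jacobian_det_density <- function(rho_bar, gamma, eta) {
  a <- gamma / eta
  if (inherits(rho_bar, "field1d")) {
    field1d(1 + a * spectral_deriv(rho_bar$values, 2L), t = rho_bar$t)
  } else if (inherits(rho_bar, "field2d")) {
    H <- spectral_hessian2d(rho_bar$values)
    field2d((1 + a * H$xx) * (1 + a * H$yy) - (a * H$xy)^2, t = rho_bar$t)
  } else stop("rho_bar must be a field1d or field2d")
}
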