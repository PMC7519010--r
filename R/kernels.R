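#' Micro-scale interaction kernel specification
#'
#' Defines an interaction potential between particles. Two families are
#' supported:
#' \describe{
#'   \item{`quadratic_compact`}{Compactly supported potential whose pushing
#'     force decreases linearly with distance and is continuous at the edge
#'     of the support. In 1D: \eqn{\phi(x) = C \frac{3}{2 r}(1 - |x|/r)^2}
#'     for \eqn{|x| < r}, zero outside, with potential mass
#'     \eqn{\int \phi = C}. In 2D:
#'     \eqn{\phi(x) = \frac{3A}{2 r^3 \pi}(r - |x|)^2} on the disc of
#'     radius \eqn{r}.}
#'   \item{`exponential`}{1D kernel without compact support, defined through
#'     its radial force profile \eqn{\varphi(r) = C e^{-r/r_I}/(2 r_I^2)},
#'     i.e. \eqn{\phi'(x) = \varphi(|x|)\,\mathrm{sign}(x)}.}
#' }
#' The sign of `amplitude` encodes attraction vs. repulsion; flipping it
#' leaves the obstacle-induced macroscopic kernel \eqn{W' } unchanged (it
#' enters only squared).
#'
#' @param family `"quadratic_compact"` or `"exponential"`.
#' @param amplitude signed amplitude (`C` in 1D, `A` in 2D); must be nonzero.
#' @param range interaction range \eqn{r_I} (or \eqn{r_R}), in units of the
#'   domain length (domain nondimensionalised to 1).
#' @param dimension spatial dimension, 1 or 2. The exponential family is
#'   implemented in 1D only.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("quadratic_compact", "exponential"),
                        amplitude, range, dimension = 1L) {
  family <- match.arg(family)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            is.numeric(range), length(range) == 1L, is.finite(range))
  if (range <= 0) stop("kernel range must be positive")
  if (amplitude == 0) stop("kernel amplitude must be nonzero")
  dimension <- as.integer(dimension)
  if (!dimension %in% c(1L, 2L)) stop("dimension must be 1 or 2")
  if (family == "exponential" && dimension != 1L)
    stop("unsupported family/dimension combination: exponential kernel is 1D only")
  structure(list(family = family, amplitude = amplitude,
                 range = range, dimension = dimension),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s, %dD, amplitude %g, range %g, mass %g\n",
              x$family, x$dimension, x$amplitude, x$range, kernel_mass(x)))
  invisible(x)
}

is_kernel_spec <- function(x) inherits(x, "kernel_spec")

#' Evaluate the interaction potential
#'
#' @param spec a [kernel_spec()].
#' @param x displacement(s). For `dimension = 1` a numeric vector; for
#'   `dimension = 2` either a two-column matrix of displacement vectors or a
#'   numeric vector interpreted as radial distances.
#' @return Potential value(s) \eqn{\phi(x)}; zero outside the support for the
#'   compact family.
#' @export
kernel_value <- function(spec, x) {
  stopifnot(is_kernel_spec(spec))
  if (spec$dimension == 2L && is.matrix(x)) x <- sqrt(rowSums(x^2))
  s <- abs(x)
  r <- spec$range
  A <- spec$amplitude
  if (spec$family == "quadratic_compact") {
    if (spec$dimension == 1L) {
      ifelse(s < r, A * 3 / (2 * r) * (1 - s / r)^2, 0)
    } else {
      ifelse(s < r, 3 * A / (2 * r^3 * pi) * (r - s)^2, 0)
    }
  } else { # exponential, 1D: antiderivative of the force profile, ->0 at infinity
    -A / (2 * r) * exp(-s / r)
  }
}

#' Radial force profile
#'
#' The odd force \eqn{\phi'} is written as
#' \eqn{\phi'(x) = \varphi(|x|)\,\mathrm{sign}(x)} with the convention
#' \eqn{\mathrm{sign}(0) = 0}. This returns \eqn{\varphi(r)} for
#' \eqn{r \ge 0} (1D families).
#'
#' @param spec a 1D [kernel_spec()].
#' @param r nonnegative distances.
#' @export
kernel_force_profile <- function(spec, r) {
  stopifnot(is_kernel_spec(spec), spec$dimension == 1L, all(r >= 0))
  A <- spec$amplitude; ri <- spec$range
  if (spec$family == "quadratic_compact") {
    ifelse(r < ri, -3 * A / ri^2 * (1 - r / ri), 0)
  } else {
    A / (2 * ri^2) * exp(-r / ri)
  }
}

#' Evaluate the interaction force \eqn{\phi'}
#'
#' For 1D specs returns the scalar derivative \eqn{\phi'(x)}, an odd function
#' with \eqn{\phi'(0) = 0} (the `sign(0) = 0` convention). For 2D specs `x`
#' must be a two-column matrix of displacement vectors and the gradient
#' \eqn{\nabla\phi} is returned row-wise.
#'
#' @inheritParams kernel_value
#' @export
kernel_force <- function(spec, x) {
  stopifnot(is_kernel_spec(spec))
  if (spec$dimension == 1L) {
    kernel_force_profile(spec, abs(x)) * sign(x)
  } else {
    if (!is.matrix(x) || ncol(x) != 2L)
      stop("2D kernel_force expects a two-column matrix of displacements")
    s <- sqrt(rowSums(x^2))
    r <- spec$range; A <- spec$amplitude
    mag <- ifelse(s < r & s > 0, -3 * A / (r^3 * pi) * (r - s), 0)
    out <- x * ifelse(s > 0, mag / s, 0)
    out[s == 0, ] <- 0
    out
  }
}

#' Kernel mass \eqn{\int \phi}
#'
#' In 1D the quadratic compact kernel has mass equal to its amplitude; the
#' SPP self-repulsion mass \eqn{\mu = \int\psi} used by the macroscopic model
#' is obtained this way.
#'
#' @param spec a [kernel_spec()].
#' @export
kernel_mass <- function(spec) {
  stopifnot(is_kernel_spec(spec))
  A <- spec$amplitude; r <- spec$range
  if (spec$family == "quadratic_compact") {
    if (spec$dimension == 1L) A else A * r / 4
  } else {
    -A
  }
}

#' Fourier transform \eqn{\hat\phi_k} of a 1D kernel
#'
#' \eqn{\hat\phi_k = \int e^{-ikx} \phi(x)\,dx}, real-valued since \eqn{\phi}
#' is even. For the quadratic compact family the closed form
#' \eqn{\hat\phi_k = 6C \frac{r k - \sin(r k)}{(r k)^3}} is used (with its
#' continuous limit \eqn{\hat\phi_0 = C}); other families fall back to
#' adaptive quadrature.
#'
#' @param spec a 1D [kernel_spec()].
#' @param k wavenumber(s).
#' @export
kernel_fourier <- function(spec, k) {
  stopifnot(is_kernel_spec(spec), spec$dimension == 1L)
  if (spec$family == "quadratic_compact") {
    u <- spec$range * k
    small <- abs(u) < 1e-4
    out <- numeric(length(u))
    # series 6(u - sin u)/u^3 = 1 - u^2/20 + u^4/840 - ...
    out[small] <- 1 - u[small]^2 / 20 + u[small]^4 / 840
    ub <- u[!small]
    out[!small] <- 6 * (ub - sin(ub)) / ub^3
    spec$amplitude * out
  } else {
    vapply(k, function(kk) {
      2 * stats::integrate(function(x) kernel_value(spec, x) * cos(kk * x),
                           0, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
}

#' Obstacle-induced macroscopic interaction kernel \eqn{W = \phi' * \phi'}
#'
#' Builds the effective SPP--SPP interaction kernel mediated by displaced
#' obstacles by discrete self-convolution of the sampled micro force
#' \eqn{\phi'}. \eqn{W} is even with compact support on
#' \eqn{[-2 r_I, 2 r_I]} for a compactly supported \eqn{\phi}; its
#' derivative \eqn{W' = \phi'' * \phi'} is discontinuous at the origin, so
#' the two one-sided limits at 0 are reported separately
#' (\eqn{W'(0^+) = 2\varphi(0)^2 > 0}: short-range attraction regardless of
#' the sign of the micro interaction).
#'
#' @param spec a 1D [kernel_spec()].
#' @param n number of samples across the sampling interval
#'   `[-R, R]`; `R = range` for the compact family and
#'   `R = truncation * range` for the exponential family. At least 64 samples
#'   must fall inside the support.
#' @param truncation truncation radius for non-compact kernels, in multiples
#'   of `range` (default 10; the neglected tail of \eqn{\varphi} is of order
#'   \eqn{e^{-10}}).
#' @return An object of class `macro_kernel`: grid `x`, values `W`, grid
#'   derivative `Wprime` (with the `sign(0)=0` convention at the origin
#'   node), one-sided limits `Wprime_0plus`/`Wprime_0minus`, and spacing `h`.
#' @export
macro_kernel <- function(spec, n = 2048L, truncation = 10) {
  stopifnot(is_kernel_spec(spec), spec$dimension == 1L)
  R <- if (spec$family == "quadratic_compact") spec$range else truncation * spec$range
  m <- as.integer(ceiling(n / 2))
  h <- R / m
  n_inside <- 2 * floor(spec$range / h)
  if (n_inside < 64)
    stop(sprintf("resolution too coarse: %d samples inside the support, need >= 64",
                 n_inside))
  x <- h * seq(-m, m)
  a <- kernel_force(spec, x)      # odd; node at 0 holds the jump average 0
  W <- h * stats::convolve(a, rev(a), type = "open")
  xw <- h * seq(-2 * m, 2 * m)
  # At lag 0 the integrand phi'(y)phi'(-y) is continuous with value
  # -varphi(0)^2 at y = 0, not the sampled product 0; restore that node.
  W[2 * m + 1] <- W[2 * m + 1] - h * kernel_force_profile(spec, 0)^2
  L <- length(xw)
  # central differences away from the origin; the origin node keeps the
  # sign(0) = 0 convention, and the one-sided limits are reported separately
  Wp <- numeric(L)
  Wp[2:(L - 1)] <- (W[3:L] - W[1:(L - 2)]) / (2 * h)
  Wp[1] <- (W[2] - W[1]) / h
  Wp[L] <- (W[L] - W[L - 1]) / h
  i0 <- 2 * m + 1
  Wp[i0] <- 0
  wp_plus  <- (-3 * W[i0] + 4 * W[i0 + 1] - W[i0 + 2]) / (2 * h)
  wp_minus <- (3 * W[i0] - 4 * W[i0 - 1] + W[i0 - 2]) / (2 * h)
  structure(list(x = xw, W = W, Wprime = Wp,
                 Wprime_0plus = wp_plus, Wprime_0minus = wp_minus,
                 h = h, spec = spec, method = "numeric_convolution"),
            class = "macro_kernel")
}

#' @export
print.macro_kernel <- function(x, ...) {
  cat(sprintf("<macro_kernel> W = phi'*phi' of a %s kernel; h = %g, W'(0+) = %g\n",
              x$spec$family, x$h, x$Wprime_0plus))
  invisible(x)
}

#' Closed-form macroscopic force for the exponential micro-kernel
#'
#' For the exponential radial force profile
#' \eqn{\varphi(r) = C e^{-r/r_I}/(2 r_I^2)} the self-convolution can be done
#' analytically:
#' \deqn{W'(x) = \frac{C^2}{4 r_I^5} e^{-|x|/r_I} (2 r_I - |x|)\,
#'   \mathrm{sign}(x),}
#' attractive for \eqn{|x| < 2 r_I} and repulsive beyond. Serves as the
#' independent oracle for [macro_kernel()] on this family.
#'
#' @param C amplitude of the micro kernel.
#' @param r_I range of the micro kernel.
#' @param x displacement(s).
#' @export
macro_kernel_exponential_wprime <- function(C, r_I, x) {
  stopifnot(r_I > 0)
  C^2 / (4 * r_I^5) * exp(-abs(x) / r_I) * (2 * r_I - abs(x)) * sign(x)
}
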