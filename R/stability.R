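# Linear stability of the constant state of the 1D macroscopic model:
# dispersion relation, stability criterion, pattern-size prediction, and a
# linearized-simulation oracle.

noise_factor <- function(k, delta) {
  if (delta > 0) (1 - exp(-delta * k^2)) / delta else k^2
}

#' Dispersion relation of the constant steady state
#'
#' Complex growth rate \eqn{\alpha(k)} of a perturbation
#' \eqn{e^{ikx + \alpha t}} of \eqn{\rho_g \equiv \rho_0}:
#' \deqn{\alpha(k) = -i\,\frac{k c_1}{D(k)} + \frac{\rho_0}{\zeta} k^2\,
#'   \frac{\frac{\gamma}{\eta\delta}(1 - e^{-\delta k^2})\hat\phi_k^2 -
#'   \mu}{D(k)}, \qquad
#'   D(k) = 1 + \gamma^2\frac{\rho_0}{\eta\zeta}k^2\hat\phi_k^2.}
#' For \eqn{\delta = 0} the analytic limit
#' \eqn{(1-e^{-\delta k^2})/\delta \to k^2} is used. The denominator
#' \eqn{D(k)} stems from the order-\eqn{\gamma^2} memory term of the
#' obstacle closure; it never changes the sign of \eqn{\Re\alpha}, only its
#' magnitude.
#'
#' @param k wavenumber(s), real.
#' @param params a [macro_params()].
#' @param gamma2_denominator logical; drop the memory-term denominator to
#'   obtain the pure order-\eqn{\gamma} rate
#'   \eqn{\Re\alpha = \frac{\rho_0}{\zeta}k^2
#'   (\frac{\gamma}{\eta}(k\hat\phi_k)^2 - \mu)} (with \eqn{\delta = 0}).
#' @return Complex vector \eqn{\alpha(k)}.
#' @export
dispersion <- function(k, params, gamma2_denominator = TRUE) {
  stopifnot(inherits(params, "macro_params"))
  phat2 <- kernel_fourier(params$phi, k)^2
  nf <- noise_factor(k, params$delta)
  D <- if (gamma2_denominator)
    1 + params$gamma^2 * params$rho0 / (params$eta * params$zeta) * k^2 * phat2
  else rep(1, length(k))
  re <- params$rho0 / params$zeta * k^2 *
    (params$gamma / params$eta * nf * phat2 - params$mu) / D
  im <- -k * params$c1 / D
  complex(real = re, imaginary = im)
}

# sup over k > 0 of nf(k) * phat_k^2 : grid scan plus local refinement
sup_gain_real_line <- function(params) {
  r <- params$phi$range
  gain <- function(k) noise_factor(k, params$delta) *
    kernel_fourier(params$phi, k)^2
  ks <- seq(1e-3, 6 * pi / r, length.out = 2048)
  g <- gain(ks)
  i <- which.max(g)
  lo <- ks[max(1, i - 2)]; hi <- ks[min(length(ks), i + 2)]
  opt <- stats::optimize(gain, c(lo, hi), maximum = TRUE, tol = 1e-12)
  list(k = opt$maximum, value = opt$objective)
}

default_l_cut <- function(params) {
  max(32L, as.integer(ceiling(2 / params$phi$range)))
}

#' Linear stability verdict for the constant state
#'
#' The constant state is linearly stable iff
#' \eqn{\max_{k\in K}\frac{1}{\delta}(1 - e^{-\delta k^2})\hat\phi_k^2 <
#' \mu\eta/\gamma}. Both admissible mode sets are reported: the real line
#' (whole-space problem, `domain = "real"`) and the integer modes
#' \eqn{K = 2\pi\mathbb{Z}} of the unit torus (`domain = "torus"`). The
#' real-line criterion is sufficient for torus stability but not necessary,
#' since the real-line maximiser \eqn{k = \pi/r_I} is typically not an
#' integer mode. Obstacle noise \eqn{\delta > 0} only ever stabilises
#' (\eqn{(1-e^{-\delta k^2})/\delta \le k^2}).
#'
#' @param params a [macro_params()].
#' @param domain `"torus"` or `"real"`.
#' @param l_cut truncation of the integer mode set; the default covers all
#'   modes with non-negligible kernel gain, and doubling it does not change
#'   the verdict.
#' @return List with `stable`, `margin` (`lhs - rhs`, negative when stable),
#'   `lhs`, `rhs`, and the maximising wavenumber `k_max`.
#' @export
stability_criterion <- function(params, domain = c("torus", "real"),
                                l_cut = NULL) {
  stopifnot(inherits(params, "macro_params"))
  domain <- match.arg(domain)
  if (params$gamma == 0)
    return(list(stable = TRUE, margin = -Inf, lhs = 0, rhs = Inf, k_max = NA))
  rhs <- params$mu * params$eta / params$gamma
  if (domain == "real") {
    s <- sup_gain_real_line(params)
    lhs <- s$value; kmax <- s$k
  } else {
    if (is.null(l_cut)) l_cut <- default_l_cut(params)
    ks <- 2 * pi * seq_len(l_cut)
    g <- noise_factor(ks, params$delta) * kernel_fourier(params$phi, ks)^2
    lhs <- max(g); kmax <- ks[which.max(g)]
  }
  list(stable = lhs < rhs, margin = lhs - rhs, lhs = lhs, rhs = rhs,
       k_max = kmax)
}

#' Predicted pattern size from the dispersion relation
#'
#' Scans the torus modes \eqn{k = 2\pi l}, \eqn{l = 1, \dots, l_{cut}}, for
#' the integer mode maximising \eqn{\Re\alpha}. In the unstable regime the
#' expected pattern size is \eqn{P = 1/l_{max}}: the reciprocal of the
#' number of clusters that the fastest-growing perturbation seeds. Ties are
#' broken towards the smaller mode.
#'
#' @param params a [macro_params()].
#' @param l_cut truncation of the mode scan.
#' @return Object of class `dispersion_result`: `l` (modes), `alpha`
#'   (complex rates), `stable`, `l_max`, `k_max`, `P` (`NA` when no pattern
#'   is predicted).
#' @export
predicted_pattern_size <- function(params, l_cut = NULL) {
  stopifnot(inherits(params, "macro_params"))
  if (is.null(l_cut)) l_cut <- default_l_cut(params)
  l <- seq_len(l_cut)
  alpha <- dispersion(2 * pi * l, params)
  re <- Re(alpha)
  stable <- max(re) <= 0
  if (stable) {
    res <- list(l = l, alpha = alpha, stable = TRUE,
                l_max = NA_integer_, k_max = NA_real_, P = NA_real_)
  } else {
    lm <- l[which.max(re)]   # which.max breaks ties towards smaller l
    res <- list(l = l, alpha = alpha, stable = FALSE,
                l_max = lm, k_max = 2 * pi * lm, P = 1 / lm)
  }
  structure(res, class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  if (x$stable) cat("<dispersion_result> stable: no pattern predicted\n")
  else cat(sprintf(
    "<dispersion_result> unstable: l_max = %d, pattern size P = %.4g, Re alpha(l_max) = %.4g\n",
    x$l_max, x$P, max(Re(x$alpha))))
  invisible(x)
}

#' Measure a growth rate by integrating the linearized equation
#'
#' Independent check of [dispersion()]: integrates the linearized density
#' equation \eqn{\partial_t\rho + c_1\partial_x\rho =
#' \frac{\rho_0}{\zeta}(\mu\partial_x^2\rho + \partial_x^2\bar\rho_f)} in
#' real space (RK4, pseudospectral derivatives) for a single-mode initial
#' perturbation \eqn{\rho_0 + a\cos(2\pi l x)}, then fits the log-amplitude
#' slope and phase drift of the complex mode amplitude. The obstacle closure
#' is the leading-order one (with noise blur when \eqn{\delta > 0}), i.e.
#' the measured rate corresponds to `dispersion(..., gamma2_denominator =
#' FALSE)`; at the stiff-spring parameter scales of interest the two differ
#' by parts in \eqn{10^{5}}.
#'
#' @param l integer torus mode.
#' @param amplitude initial perturbation amplitude (linear regime; the run
#'   aborts if amplification exceeds 1e6).
#' @param params a [macro_params()].
#' @param T integration time; by default long enough to amplify/decay the
#'   mode by a factor ~50, capped at 40.
#' @param n grid size (must resolve the mode).
#' @return List with `growth_rate`, `phase_speed`, fitted over the sample
#'   window, plus the per-sample amplitudes.
#' @export
simulate_linearized <- function(l, amplitude = 1e-6, params, T = NULL,
                                n = 256) {
  stopifnot(inherits(params, "macro_params"), l >= 1, n >= 4 * l)
  k_mode <- 2 * pi * l
  # a priori rate bound for step control (a bound, not the measurement)
  phat_mode2 <- kernel_fourier(params$phi, k_mode)^2
  rate_bound <- params$rho0 / params$zeta * k_mode^2 *
    (params$mu + params$gamma / params$eta *
       noise_factor(k_mode, params$delta) * phat_mode2) +
    params$c1 * k_mode
  dt <- 0.02 / rate_bound
  if (is.null(T)) {
    re_guess <- params$rho0 / params$zeta * k_mode^2 *
      (params$gamma / params$eta * noise_factor(k_mode, params$delta) *
         kernel_fourier(params$phi, k_mode)^2 - params$mu)
    T <- min(40, log(50) / max(abs(re_guess), 0.25))
  }
  x <- (seq_len(n) - 1) / n
  u <- amplitude * cos(k_mode * x)          # deviation from rho0
  k <- 2 * pi * fft_modes(n)
  nyq <- if (n %% 2 == 0) n / 2 + 1 else 0L
  ik <- 1i * k; if (nyq > 0) ik[nyq] <- 0
  phat <- kernel_fourier(params$phi, k)
  nf <- noise_factor(k, params$delta)
  lin_rhs <- function(u) {
    uhat <- stats::fft(u)
    # rho_f - 1 = -(gamma/eta) nf(k) phat uhat ; rbar_f = phat * (rho_f - 1)
    rbf_hat <- -params$gamma / params$eta * nf * phat^2 * uhat
    lap_rbf <- Re(stats::fft(-k^2 * rbf_hat, inverse = TRUE)) / n
    lap_u <- Re(stats::fft(-k^2 * uhat, inverse = TRUE)) / n
    du <- Re(stats::fft(ik * uhat, inverse = TRUE)) / n
    -params$c1 * du + params$rho0 / params$zeta *
      (params$mu * lap_u + lap_rbf)
  }
  nsteps <- max(20L, as.integer(ceiling(T / dt)))
  dt <- T / nsteps
  sample_every <- max(1L, nsteps %/% 200L)
  ts <- c(); amps <- c(); phases <- complex()
  mode_amp <- function(u) stats::fft(u)[l + 1] / n
  record <- function(t, u) {
    ts <<- c(ts, t); a <- mode_amp(u)
    amps <<- c(amps, Mod(a)); phases <<- c(phases, a)
  }
  record(0, u)
  for (s in seq_len(nsteps)) {
    k1 <- lin_rhs(u); k2 <- lin_rhs(u + dt / 2 * k1)
    k3 <- lin_rhs(u + dt / 2 * k2); k4 <- lin_rhs(u + dt * k3)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s %% sample_every == 0 || s == nsteps) record(s * dt, u)
    if (max(abs(u)) > 1e6 * amplitude)
      stop("simulate_linearized: amplitude grew beyond 1e6x; fit window exceeded")
  }
  # fit window: amplitudes within [2x, 100x] of the initial one when
  # growing; full record otherwise
  ratio <- amps / amps[1]
  sel <- if (ratio[length(ratio)] > 2) which(ratio >= 2 & ratio <= 100) else
    seq_along(ts)
  if (length(sel) < 5) sel <- seq_along(ts)
  fit <- stats::lm(log(amps[sel]) ~ ts[sel])
  growth <- unname(stats::coef(fit)[2])
  ang <- Arg(phases)
  dphi <- diff(ang)
  dphi <- (dphi + pi) %% (2 * pi) - pi      # unwrap
  phase <- cumsum(c(ang[1], dphi))
  pfit <- stats::lm(phase[sel] ~ ts[sel])
  omega <- unname(stats::coef(pfit)[2])     # = Im(alpha)
  list(growth_rate = growth, phase_speed = -omega / k_mode,
       times = ts[sel], amplitudes = amps[sel], l = l)
}
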