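# Stochastic individual-based model: Vicsek-type self-propelled particles
# (unit speed, orientation alignment with rotational noise) coupled to
# obstacles tethered by Hookean springs, on the unit torus in 1D or 2D.
# Overdamped Euler-Maruyama dynamics:
#   dX_i = [-(kappa/eta)(X_i - Y_i) - (1/eta)(1/M) sum_k grad phi(X_i - Z_k)] dt
#          + sqrt(2 d_o) dB_i
#   dZ_k = [alpha_k - (1/zeta)(1/N) sum_i grad phi(Z_k - X_i)
#                  - (1/zeta)(1/M) sum_{l!=k} grad psi(Z_k - Z_l)] dt
#   dtheta_k = nu sin(thetabar_k - theta_k) dt + sqrt(2 d_s) dW_k   (2D)
# In 1D the orientation equation is dropped and all particles self-propel to
# the right.

#' Parameters of the individual-based SPP--obstacle model
#'
#' Nondimensionalised so the domain is the unit torus and the
#' self-propulsion speed is 1 (lengths in domain widths, times in domain
#' crossing times).
#'
#' @param N number of obstacles.
#' @param M number of SPPs.
#' @param kappa tether spring stiffness \eqn{\kappa > 0}.
#' @param eta obstacle friction \eqn{\eta > 0}.
#' @param zeta SPP friction \eqn{\zeta > 0}.
#' @param nu alignment frequency \eqn{\nu \ge 0} (2D only).
#' @param d_s SPP orientational noise intensity \eqn{d_s \ge 0}.
#' @param d_o obstacle positional noise intensity \eqn{d_o \ge 0}.
#' @param r_A alignment radius (2D only).
#' @param phi SPP--obstacle interaction [kernel_spec()] (matching
#'   `dimension`), or `NULL` for no interaction.
#' @param psi SPP self-repulsion [kernel_spec()], or `NULL`.
#' @param dimension 1 or 2.
#' @param dt Euler--Maruyama step; default `min(0.1 * gamma, 1e-3)` with
#'   \eqn{\gamma = \eta/\kappa} the fastest (spring) time scale.
#' @export
ibm_params <- function(N, M, kappa, eta = 1, zeta, nu = 0, d_s = 0, d_o = 0,
                       r_A = 0, phi = NULL, psi = NULL, dimension = 2L,
                       dt = NULL) {
  dimension <- as.integer(dimension)
  stopifnot(N >= 1, M >= 1, kappa > 0, eta > 0, zeta > 0, nu >= 0,
            d_s >= 0, d_o >= 0, r_A >= 0, dimension %in% c(1L, 2L))
  for (kn in list(phi, psi)) if (!is.null(kn)) {
    stopifnot(is_kernel_spec(kn))
    if (kn$dimension != dimension)
      stop("kernel dimension does not match model dimension")
    r_eff <- if (kn$family == "quadratic_compact") kn$range else 10 * kn$range
    if (r_eff >= 0.5)
      stop("interaction radius >= half the domain: minimum-image convention invalid")
  }
  if (r_A >= 0.5) stop("alignment radius >= half the domain")
  gamma <- eta / kappa
  if (is.null(dt)) dt <- min(0.1 * gamma, 1e-3)
  stopifnot(dt > 0)
  structure(list(N = as.integer(N), M = as.integer(M), kappa = kappa,
                 eta = eta, zeta = zeta, nu = nu, d_s = d_s, d_o = d_o,
                 r_A = r_A, phi = phi, psi = psi, dimension = dimension,
                 dt = dt, gamma = gamma),
            class = "ibm_params")
}

#' @export
print.ibm_params <- function(x, ...) {
  cat(sprintf(
    "<ibm_params> %dD, N=%d obstacles, M=%d SPPs, kappa=%g, zeta=%g, nu=%g, dt=%g\n",
    x$dimension, x$N, x$M, x$kappa, x$zeta, x$nu, x$dt))
  invisible(x)
}

wrap01 <- function(x) x - floor(x)

as_coord_matrix <- function(x, dim) {
  if (is.matrix(x)) x else matrix(x, ncol = dim)
}

#' Initialise the particle state
#'
#' Anchors are drawn uniformly on the torus or placed on a regular lattice;
#' obstacles start exactly at their anchors (`X = Y`); SPP positions are
#' uniform; orientations are uniform on \eqn{[0, 2\pi)} in 2D and fixed
#' rightward in 1D. Fully reproducible given `seed`.
#'
#' @param params an [ibm_params()].
#' @param anchor_layout `"uniform_random"` or `"lattice"` (in 2D the lattice
#'   needs a square obstacle count).
#' @param seed RNG seed.
#' @return An object of class `ibm_state` with fields `X`, `Y`, `Z`,
#'   `theta`, `t`.
#' @export
ibm_init <- function(params, anchor_layout = c("uniform_random", "lattice"),
                     seed = 1) {
  stopifnot(inherits(params, "ibm_params"))
  anchor_layout <- match.arg(anchor_layout)
  set.seed(seed)
  d <- params$dimension
  Y <- if (anchor_layout == "lattice") {
    if (d == 1L) matrix((seq_len(params$N) - 1) / params$N, ncol = 1)
    else {
      g <- round(sqrt(params$N))
      if (g * g != params$N)
        stop("2D lattice anchors need a square obstacle count")
      as.matrix(expand.grid((seq_len(g) - 1) / g, (seq_len(g) - 1) / g))
    }
  } else matrix(stats::runif(params$N * d), ncol = d)
  dimnames(Y) <- NULL
  Z <- matrix(stats::runif(params$M * d), ncol = d)
  theta <- if (d == 2L) stats::runif(params$M, 0, 2 * pi) else NULL
  structure(list(X = Y, Y = Y, Z = Z, theta = theta, t = 0),
            class = "ibm_state")
}

#' @export
print.ibm_state <- function(x, ...) {
  cat(sprintf("<ibm_state> t = %g, %d obstacles, %d SPPs (%dD)\n",
              x$t, nrow(x$X), nrow(x$Z), ncol(x$X)))
  invisible(x)
}

kern_args <- function(kn) {
  if (is.null(kn)) list(fam = 0L, A = 0, r = 1, active = FALSE)
  else list(fam = if (kn$family == "quadratic_compact") 0L else 1L,
            A = kn$amplitude, r = kn$range, active = TRUE)
}

#' Deterministic drift forces on obstacles and SPPs
#'
#' Pairwise interaction sums (with the mean-field 1/M, 1/N prefactors, SPP
#' self-repulsion excluding the particle itself, minimum-image displacements
#' throughout) plus the tether spring. Self-propulsion is not included; the
#' integrator adds it.
#'
#' @param state an `ibm_state`.
#' @param params an [ibm_params()].
#' @param method `"cell"` for the cell-list evaluation, `"brute"` for the
#'   O(NM) double loop (identical result; used as the test oracle).
#' @return List with `obstacle` (N x dim drift) and `spp` (M x dim drift).
#' @export
ibm_forces <- function(state, params, method = c("cell", "brute")) {
  method <- match.arg(method)
  kp <- kern_args(params$phi); ks <- kern_args(params$psi)
  s <- cpp_pair_sums(state$X, state$Z, kp$fam, kp$A, kp$r, kp$active,
                     ks$fam, ks$A, ks$r, ks$active,
                     use_cells = method == "cell")
  dXY <- state$X - state$Y
  dXY <- dXY - round(dXY)
  list(obstacle = -(params$kappa / params$eta) * dXY - s$obs / params$eta,
       spp = -s$spp / params$zeta)
}

#' Vicsek mean direction per SPP
#'
#' Normalised mean flux \eqn{\bar\alpha_k = J_k/|J_k|} with
#' \eqn{J_k = \sum_{|Z_k - Z_j| \le r_A} \alpha_j} (the sum includes
#' \eqn{j = k}; torus distances). Where \eqn{|J_k|} vanishes the mean
#' direction is undefined and flagged, and the alignment drift is set to
#' zero for that step.
#'
#' @param state a 2D `ibm_state`.
#' @param params an [ibm_params()].
#' @param method cell-list or brute-force evaluation.
#' @return List with `alpha_bar` (M x 2, rows `NA` where undefined) and
#'   `defined` (logical vector).
#' @export
ibm_mean_direction <- function(state, params, method = c("cell", "brute")) {
  stopifnot(ncol(state$Z) == 2L)
  method <- match.arg(method)
  J <- cpp_mean_flux(state$Z, state$theta, params$r_A,
                     use_cells = method == "cell")
  nrm <- sqrt(rowSums(J^2))
  defined <- nrm > 1e-12
  ab <- J / ifelse(nrm > 1e-12, nrm, 1)
  ab[!defined, ] <- NA_real_
  list(alpha_bar = ab, defined = defined)
}

#' One Euler--Maruyama step
#'
#' Positions are updated explicitly and re-wrapped to the torus; the 2D
#' orientation dynamics on the circle reduce to the angle equation
#' \eqn{d\theta_k = \nu\sin(\bar\theta_k - \theta_k)\,dt +
#' \sqrt{2 d_s}\,dW}, which keeps \eqn{|\alpha_k| = 1} exactly. Noise draws
#' occur in fixed order (obstacles, then orientations) for reproducibility.
#'
#' @inheritParams ibm_forces
#' @export
ibm_step <- function(state, params, method = c("cell", "brute")) {
  method <- match.arg(method)
  dt <- params$dt
  if (dt * (params$nu + params$kappa / params$eta) > 0.5)
    warning("dt * (nu + kappa/eta) > 0.5: step likely unstable", call. = FALSE)
  f <- ibm_forces(state, params, method)
  X <- state$X + dt * f$obstacle
  if (params$d_o > 0)
    X <- X + sqrt(2 * params$d_o * dt) *
      matrix(stats::rnorm(length(X)), nrow = nrow(X))
  theta <- state$theta
  if (params$dimension == 2L) {
    alpha <- cbind(cos(theta), sin(theta))
    if (params$nu > 0) {
      md <- ibm_mean_direction(state, params, method)
      tb <- atan2(md$alpha_bar[, 2], md$alpha_bar[, 1])
      drift <- ifelse(md$defined, params$nu * sin(tb - theta), 0)
    } else drift <- 0
    theta <- theta + dt * drift
    if (params$d_s > 0)
      theta <- theta + sqrt(2 * params$d_s * dt) * stats::rnorm(length(theta))
  } else {
    alpha <- matrix(1, nrow = params$M, ncol = 1)
  }
  Z <- state$Z + dt * (alpha + f$spp)
  structure(list(X = wrap01(X), Y = state$Y, Z = wrap01(Z), theta = theta,
                 t = state$t + dt),
            class = "ibm_state")
}

#' Run the individual-based model
#'
#' @param params an [ibm_params()].
#' @param T final time.
#' @param save_every snapshot cadence in time units (default: 10 snapshots).
#' @param seed RNG seed (controls initial condition and noise).
#' @param anchor_layout passed to [ibm_init()].
#' @param state optional pre-built initial state (then `seed` only seeds the
#'   noise).
#' @param method neighbour-search method, see [ibm_forces()].
#' @param verbose print progress.
#' @return List with `states` (snapshots), `times`, `params`.
#' @export
ibm_run <- function(params, T, save_every = NULL, seed = 1,
                    anchor_layout = c("uniform_random", "lattice"),
                    state = NULL, method = c("cell", "brute"),
                    verbose = FALSE) {
  stopifnot(inherits(params, "ibm_params"), T >= 0)
  method <- match.arg(method)
  anchor_layout <- match.arg(anchor_layout)
  if (is.null(state)) state <- ibm_init(params, anchor_layout, seed)
  else set.seed(seed)
  if (is.null(save_every)) save_every <- if (T > 0) T / 10 else 1
  nsteps <- if (T > 0) max(1L, as.integer(round(T / params$dt))) else 0L
  stride <- max(1L, as.integer(round(save_every / params$dt)))
  states <- list(state)
  if (params$dimension == 1L) {
    # orientation-free 1D dynamics: compiled inner loop between snapshots
    kp <- kern_args(params$phi); ks <- kern_args(params$psi)
    done <- 0L
    while (done < nsteps) {
      todo <- min(stride, nsteps - done)
      r <- cpp_run_1d(state$X[, 1], state$Y[, 1], state$Z[, 1],
                      params$kappa, params$eta, params$zeta, params$d_o,
                      kp$fam, kp$A, kp$r, kp$active,
                      ks$fam, ks$A, ks$r, ks$active,
                      params$dt, todo, method == "cell")
      done <- done + todo
      state <- structure(list(X = matrix(r$X, ncol = 1), Y = state$Y,
                              Z = matrix(r$Z, ncol = 1), theta = NULL,
                              t = state$t + todo * params$dt),
                         class = "ibm_state")
      if (any(!is.finite(state$X)) || any(!is.finite(state$Z)))
        stop(sprintf("ibm_run: non-finite coordinates at t = %.4g", state$t))
      states[[length(states) + 1L]] <- state
      if (verbose) message(sprintf("t = %.3f", state$t))
    }
    return(list(states = states,
                times = vapply(states, function(s) s$t, numeric(1)),
                params = params))
  }
  for (s in seq_len(nsteps)) {
    state <- ibm_step(state, params, method)
    if (s %% stride == 0L || s == nsteps) {
      if (any(!is.finite(state$X)) || any(!is.finite(state$Z)))
        stop(sprintf("ibm_run: non-finite coordinates at t = %.4g", state$t))
      states[[length(states) + 1L]] <- state
      if (verbose) message(sprintf("t = %.3f", state$t))
    }
  }
  list(states = states, times = vapply(states, function(s) s$t, numeric(1)),
       params = params)
}

#' Relative SPP neighbourhood density
#'
#' For each SPP, the number of SPPs within a torus disc of the given radius
#' (including itself) divided by the expected count for a uniform field
#' (\eqn{M\pi r^2}); 1 in expectation for a uniform configuration.
#'
#' @param state a 2D `ibm_state`.
#' @param radius disc radius (< 0.5).
#' @export
neighborhood_density <- function(state, radius) {
  stopifnot(ncol(state$Z) == 2L)
  if (radius >= 0.5) stop("radius must be < 0.5 on the unit torus")
  Z <- state$Z
  M <- nrow(Z)
  dx <- outer(Z[, 1], Z[, 1], "-"); dx <- dx - round(dx)
  dy <- outer(Z[, 2], Z[, 2], "-"); dy <- dy - round(dy)
  counts <- rowSums(dx^2 + dy^2 <= radius^2)
  counts / (M * pi * radius^2)
}

#' Circular variance of SPP directions
#'
#' \eqn{1 - |\langle\alpha_k\rangle|}, in `[0, 1]`: 0 for perfect alignment,
#' 1 for fully balanced directions. The global-alignment diagnostic.
#'
#' @param state a 2D `ibm_state`.
#' @export
direction_variance <- function(state) {
  stopifnot(!is.null(state$theta))
  1 - sqrt(mean(cos(state$theta))^2 + mean(sin(state$theta))^2)
}

#' Obstacle displacement magnitudes
#'
#' Torus-aware \eqn{|X_i - Y_i|} per obstacle.
#'
#' @param state an `ibm_state`.
#' @export
obstacle_displacement <- function(state) {
  d <- state$X - state$Y
  d <- d - round(d)
  sqrt(rowSums(d^2))
}
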