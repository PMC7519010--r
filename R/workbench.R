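# Presets binding the reference parameter sets, YAML configuration, and the
# paired continuum-vs-particle comparison driver.

#' Macroscopic model presets
#'
#' Named parameter bundles for the 1D continuum experiments:
#' \describe{
#'   \item{`fig6`}{travelling clusters: \eqn{\eta=1,\ c_1=1,\ \zeta=8,\
#'     \gamma=2\times10^{-3},\ \mu=5\times10^{-4}}, quadratic kernel
#'     \eqn{r_I=0.18,\ C=0.25}.}
#'   \item{`fig7_repulsive` / `fig7_attractive`}{same bundle with
#'     \eqn{C=+0.25} / \eqn{C=-0.25}; paired with a Gaussian initial bump to
#'     show that the SPP dynamics do not depend on the sign of the micro
#'     interaction.}
#'   \item{`fig8`}{pattern-size scan family: \eqn{\mu=6.7\times10^{-3},\
#'     C=0.17}, with `r_I` supplied by the caller.}
#' }
#'
#' @param name preset name.
#' @param r_I interaction radius (required for `fig8`).
#' @param closure obstacle closure, see [macro_params()].
#' @export
macro_preset <- function(name = c("fig6", "fig7_repulsive", "fig7_attractive",
                                  "fig8"),
                         r_I = NULL, closure = "order1") {
  name <- match.arg(name)
  if (name == "fig8") {
    if (is.null(r_I)) stop("preset 'fig8' needs an interaction radius r_I")
    phi <- kernel_spec("quadratic_compact", amplitude = 0.17, range = r_I)
    return(macro_params(c1 = 1, mu = 6.7e-3, zeta = 8, eta = 1, gamma = 2e-3,
                        rho0 = 1, phi = phi, closure = closure))
  }
  C <- if (name == "fig7_attractive") -0.25 else 0.25
  phi <- kernel_spec("quadratic_compact", amplitude = C, range = 0.18)
  macro_params(c1 = 1, mu = 5e-4, zeta = 8, eta = 1, gamma = 2e-3, rho0 = 1,
               phi = phi, closure = closure)
}

#' Individual-based model presets
#'
#' The three 2D pattern regimes (shared parameters
#' \eqn{d_o=0,\ \eta=1,\ d_s=0.1,\ A_I=1}, all interaction radii equal):
#' \describe{
#'   \item{`moving_clusters`}{\eqn{\kappa=100,\ \zeta=1,\ \nu=10,\
#'     r_I=0.05,\ A_R=0.01}.}
#'   \item{`trails`}{\eqn{\kappa=2.5,\ \zeta=10,\ \nu=100,\ r_I=0.15,\
#'     A_R=0.002}.}
#'   \item{`travelling_bands`}{\eqn{\kappa=100,\ \zeta=40,\ \nu=10,\
#'     r_I=0.05,\ A_R=0.002}.}
#' }
#' The reference scale is \eqn{N=M=5000}; pass smaller counts for
#' desk-scale runs (the dynamics are mean-field scaled, so counts only set
#' sampling noise).
#'
#' @param name preset name.
#' @param N,M obstacle and SPP counts.
#' @export
ibm_preset <- function(name = c("moving_clusters", "trails",
                                "travelling_bands"),
                       N = 5000, M = 5000) {
  name <- match.arg(name)
  p <- switch(name,
    moving_clusters  = list(kappa = 100, zeta = 1, nu = 10, r = 0.05,
                            A_R = 0.01),
    trails           = list(kappa = 2.5, zeta = 10, nu = 100, r = 0.15,
                            A_R = 0.002),
    travelling_bands = list(kappa = 100, zeta = 40, nu = 10, r = 0.05,
                            A_R = 0.002))
  ibm_params(N = N, M = M, kappa = p$kappa, eta = 1, zeta = p$zeta,
             nu = p$nu, d_s = 0.1, d_o = 0, r_A = p$r,
             phi = kernel_spec("quadratic_compact", 1, p$r, dimension = 2L),
             psi = kernel_spec("quadratic_compact", p$A_R, p$r,
                               dimension = 2L),
             dimension = 2L)
}

#' 1D particle model matched to a macroscopic parameter set
#'
#' Builds the [ibm_params()] used in the continuum-vs-particle comparisons:
#' \eqn{N = M = 100}, \eqn{\kappa = \eta/\gamma}, the same SPP--obstacle
#' kernel as the continuum model, and a quadratic self-repulsion kernel of
#' width \eqn{r_R = 0.02} whose mass equals the continuum self-repulsion
#' mass \eqn{\mu}.
#'
#' @param mp a [macro_params()].
#' @param N,M particle counts.
#' @param r_R self-repulsion range.
#' @export
ibm_params_from_macro <- function(mp, N = 100, M = 100, r_R = 0.02) {
  stopifnot(inherits(mp, "macro_params"))
  ibm_params(N = N, M = M, kappa = mp$eta / mp$gamma, eta = mp$eta,
             zeta = mp$zeta, d_o = mp$delta / mp$gamma,
             phi = mp$phi,
             psi = kernel_spec("quadratic_compact", mp$mu, r_R,
                               dimension = 1L),
             dimension = 1L)
}

#' Paired continuum-vs-particle comparison
#'
#' Runs the 1D macroscopic model and the matched particle model at the same
#' parameters, summarises both densities at the final time, and attaches
#' the linear-stability prediction. This is the experiment behind the
#' pattern-size validation: in the unstable regime with positive obstacle
#' density the observed peak count should match the predicted mode
#' \eqn{l_{max}}.
#'
#' @param preset `"fig6"` or `"fig8"`.
#' @param r_I interaction radius (for `"fig8"`).
#' @param seed RNG seed (macro initial perturbation and particle placement).
#' @param T final time.
#' @param n_grid continuum grid size.
#' @param run_ibm logical; include the particle run.
#' @return List with `macro` and `ibm` [pattern_summary()] objects,
#'   `prediction` (a `dispersion_result`), and the final density fields.
#' @export
run_comparison <- function(preset = c("fig6", "fig8"), r_I = NULL, seed = 1,
                           T = 30, n_grid = 256, run_ibm = TRUE) {
  preset <- match.arg(preset)
  mp <- if (preset == "fig6") macro_preset("fig6") else
    macro_preset("fig8", r_I = r_I)
  pred <- predicted_pattern_size(mp)
  init <- perturbed_uniform_density(n_grid, rho0 = mp$rho0, seed = seed)
  mrun <- macro_run(init, mp, T = T, save_every = T / 4)
  mfin <- mrun$fields[[length(mrun$fields)]]
  mrf <- rho_f_order1(mfin, mp$gamma, mp$eta, mp$phi)
  macro_sum <- pattern_summary(mfin, mrf)
  ibm_sum <- NULL; ifin <- NULL
  if (run_ibm) {
    ip <- ibm_params_from_macro(mp)
    irun <- ibm_run(ip, T = T, save_every = T, seed = seed,
                    anchor_layout = "lattice")
    ist <- irun$states[[length(irun$states)]]
    ifin <- density_from_particles(ist$Z[, 1], n = n_grid)
    irf <- density_from_particles(ist$X[, 1], n = n_grid)
    ibm_sum <- pattern_summary(ifin, irf)
  }
  list(macro = macro_sum, ibm = ibm_sum, prediction = pred,
       macro_field = mfin, macro_rho_f = mrf, ibm_field = ifin,
       params = mp)
}

#' Load an experiment configuration from YAML
#'
#' Parses a config with a `model` key (`"macro"` or `"ibm"`), a `params`
#' table, and `kernel.phi` / `kernel.psi` tables (`family`, `amplitude`,
#' `range`). Cross-parameter relations are validated: when both
#' parameterisations are present, \eqn{\gamma = \eta/\kappa} and
#' \eqn{\delta = d_o\gamma} must hold. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return An [ibm_params()] or [macro_params()] object plus run settings,
#'   as a list of class `experiment_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_top <- c("model", "params", "kernel", "run")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model) || !cfg$model %in% c("macro", "ibm"))
    stop("config needs model: macro or ibm")
  p <- cfg$params
  if (is.null(p)) stop("config needs a params table")
  dim <- as.integer(p$dimension %||% 1L)
  mk_kernel <- function(tab) {
    if (is.null(tab)) return(NULL)
    kernel_spec(tab$family, tab$amplitude, tab$range, dimension = dim)
  }
  phi <- mk_kernel(cfg$kernel$phi)
  psi <- mk_kernel(cfg$kernel$psi)
  eta <- p$eta %||% 1
  if (!is.null(p$kappa) && !is.null(p$gamma) &&
      abs(p$gamma - eta / p$kappa) > 1e-12 * abs(p$gamma))
    stop("inconsistent parameters: gamma must equal eta/kappa")
  if (!is.null(p$d_o) && !is.null(p$delta) && !is.null(p$gamma) &&
      abs(p$delta - p$d_o * p$gamma) > 1e-12 * max(abs(p$delta), 1e-300))
    stop("inconsistent parameters: delta must equal d_o * gamma")
  params <- if (cfg$model == "macro") {
    gamma <- p$gamma %||% (eta / p$kappa)
    delta <- p$delta %||% ((p$d_o %||% 0) * gamma)
    macro_params(c1 = p$c1 %||% 1, mu = p$mu, zeta = p$zeta, eta = eta,
                 gamma = gamma, delta = delta, rho0 = p$rho0 %||% 1,
                 phi = phi, closure = p$closure %||% "order1")
  } else {
    kappa <- p$kappa %||% (eta / p$gamma)
    ibm_params(N = p$N, M = p$M, kappa = kappa, eta = eta, zeta = p$zeta,
               nu = p$nu %||% 0, d_s = p$d_s %||% 0, d_o = p$d_o %||% 0,
               r_A = p$r_A %||% 0, phi = phi, psi = psi, dimension = dim,
               dt = p$dt)
  }
  structure(list(model = cfg$model, params = params,
                 run = cfg$run %||% list()),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
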