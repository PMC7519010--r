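# Independent R-level oracles: plain double loops and quadrature, no cell
# lists, no FFT, no compiled code.

minimg <- function(d) d - round(d)
wrap01 <- function(x) x - floor(x)

# brute-force interaction drifts (spring included), mirroring the model
# definition directly from the kernel functions
brute_drift_r <- function(state, params) {
  X <- state$X; Y <- state$Y; Z <- state$Z
  N <- nrow(X); M <- nrow(Z); d <- ncol(X)
  gphi <- function(spec, v) {   # v: 1 x d displacement matrix
    if (d == 1L) kernel_force(spec, v[1, 1]) else
      as.numeric(kernel_force(spec, v))
  }
  fobs <- matrix(0, N, d); fspp <- matrix(0, M, d)
  for (i in seq_len(N)) {
    acc <- rep(0, d)
    if (!is.null(params$phi))
      for (k in seq_len(M)) {
        v <- minimg(X[i, ] - Z[k, ])
        acc <- acc + as.numeric(gphi(params$phi, matrix(v, 1)))
      }
    fobs[i, ] <- -(params$kappa / params$eta) * minimg(X[i, ] - Y[i, ]) -
      acc / (M * params$eta)
  }
  for (k in seq_len(M)) {
    acc <- rep(0, d)
    if (!is.null(params$phi))
      for (i in seq_len(N)) {
        v <- minimg(Z[k, ] - X[i, ])
        acc <- acc + as.numeric(gphi(params$phi, matrix(v, 1))) / N
      }
    if (!is.null(params$psi))
      for (l in seq_len(M)) {
        if (l == k) next
        v <- minimg(Z[k, ] - Z[l, ])
        acc <- acc + as.numeric(gphi(params$psi, matrix(v, 1))) / M
      }
    fspp[k, ] <- -acc / params$zeta
  }
  list(obstacle = fobs, spp = fspp)
}

# brute-force Vicsek mean flux, double loop over all pairs
brute_mean_flux_r <- function(Z, theta, r_A) {
  M <- nrow(Z)
  J <- matrix(0, M, 2)
  for (k in seq_len(M)) {
    for (j in seq_len(M)) {
      dv <- minimg(Z[k, ] - Z[j, ])
      if (sum(dv^2) <= r_A^2)
        J[k, ] <- J[k, ] + c(cos(theta[j]), sin(theta[j]))
    }
  }
  J
}

make_state <- function(X, Y, Z, theta = NULL, t = 0) {
  structure(list(X = X, Y = Y, Z = Z, theta = theta, t = t),
            class = "ibm_state")
}

# quadrature Fourier transform of a compact 1D kernel
quad_fourier <- function(spec, k) {
  vapply(k, function(kk) {
    2 * stats::integrate(function(x) kernel_value(spec, x) * cos(kk * x),
                         0, spec$range, rel.tol = 1e-12)$value
  }, numeric(1))
}
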