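# Pattern quantification shared by particle and continuum outputs:
# particle-to-grid density estimation, peak counting on the circle, and
# travelling-wave speed measurement.

#' Kernel density estimate of particle positions on the torus
#'
#' Replaces each Dirac mass of the empirical distribution by a wrapped 1D
#' Gaussian, so the field integrates to exactly 1. The bandwidth is the
#' Gaussian variance; the default \eqn{10^{-4}} (standard deviation 0.01
#' domain lengths) is small enough to resolve cluster patterns and large
#' enough to average over particle discreteness for O(100) particles. The
#' choice is delicate for smaller ensembles, so it is exposed.
#'
#' @param positions particle positions in `[0, 1)`.
#' @param variance Gaussian variance (> 0).
#' @param n grid size of the output field.
#' @return A [field1d()] with unit mass (spatial mean 1).
#' @export
density_from_particles <- function(positions, variance = 1e-4, n = 512) {
  stopifnot(length(positions) >= 1, variance > 0,
            all(positions >= 0), all(positions < 1))
  x <- (seq_len(n) - 1) / n
  sd <- sqrt(variance)
  d <- outer(x, positions, "-")
  d <- d - round(d)                         # minimum image
  v <- rowSums(stats::dnorm(d, sd = sd))
  # renormalise exactly: wrapping truncation and grid quadrature residuals
  v <- v / mean(v)
  field1d(v)
}

# circular index helper
circ <- function(i, n) ((i - 1L) %% n) + 1L

#' Count peaks of a periodic field
#'
#' Local maxima with topographic prominence at least
#' `prominence * (max - min)`, with periodic wrap-around; maxima closer than
#' `min_separation` grid cells are merged (the higher one kept). A flat
#' field has no peaks.
#'
#' @param field a [field1d()].
#' @param prominence prominence threshold as a fraction of the field range.
#' @param min_separation merge radius in grid cells.
#' @return List with `n_peaks`, `positions`, `indices`, `prominences`.
#' @export
count_peaks <- function(field, prominence = 0.2, min_separation = 2L) {
  stopifnot(inherits(field, "field1d"))
  v <- field$values
  n <- length(v)
  rng <- max(v) - min(v)
  if (rng <= .Machine$double.eps * max(abs(v), 1) * 10)
    return(list(n_peaks = 0L, positions = numeric(0), indices = integer(0),
                prominences = numeric(0)))
  left <- v[circ(seq_len(n) - 1L, n)]
  right <- v[circ(seq_len(n) + 1L, n)]
  cand <- which(v > left & v >= right)
  if (length(cand) == 0)
    return(list(n_peaks = 0L, positions = numeric(0), indices = integer(0),
                prominences = numeric(0)))
  prom <- vapply(cand, function(i) {
    # walk both ways to the nearest higher terrain, tracking the lowest col
    walk <- function(step) {
      lo <- v[i]; j <- i
      for (s in seq_len(n - 1L)) {
        j <- circ(j + step, n)
        if (v[j] > v[i]) return(lo)
        lo <- min(lo, v[j])
      }
      lo                                    # global max: full circle
    }
    v[i] - max(walk(-1L), walk(1L))
  }, numeric(1))
  keep <- prom >= prominence * rng
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) > 1) {
    # merge circularly-close maxima, higher one wins
    ord <- order(v[cand], decreasing = TRUE)
    sel <- logical(length(cand))
    for (ii in ord) {
      di <- abs(cand[ii] - cand[sel])
      di <- pmin(di, n - di)
      if (!any(sel) || all(di > min_separation)) sel[ii] <- TRUE
    }
    o2 <- order(cand[sel])
    prom <- prom[sel][o2]
    cand <- cand[sel][o2]
  }
  list(n_peaks = length(cand), positions = field$x[cand], indices = cand,
       prominences = prom)
}

#' Travelling-wave speed from two snapshots
#'
#' Displacement between two fields on the same periodic grid, found as the
#' argmax of the circular cross-correlation with sub-grid refinement by
#' quadratic interpolation of the correlation peak; speed = displacement /
#' elapsed time. Displacements are reported in \eqn{(-1/2, 1/2]} domain
#' lengths, so the elapsed time must be short enough that the pattern moves
#' less than half the domain. If the normalised correlation peak is below
#' 0.5 the fields are considered decorrelated and `NA` is returned with a
#' warning.
#'
#' @param field1,field2 [field1d()] snapshots on the same grid.
#' @param dt elapsed time `t2 - t1` (> 0).
#' @export
wave_speed <- function(field1, field2, dt) {
  stopifnot(inherits(field1, "field1d"), inherits(field2, "field1d"),
            field1$n == field2$n, dt > 0)
  n <- field1$n
  a <- field1$values - mean(field1$values)
  b <- field2$values - mean(field2$values)
  if (sum(a^2) == 0 && sum(b^2) == 0) return(0)   # two constant fields
  # C[s+1] = sum_x a(x) b(x + s): peaks at s = displacement of b vs a
  C <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / n
  Cn <- C / sqrt(sum(a^2) * sum(b^2))
  i <- which.max(Cn)
  if (Cn[i] < 0.5) {
    warning("no coherent translation: correlation peak below 0.5")
    return(NA_real_)
  }
  cm <- C[circ(i - 1L, n)]; c0 <- C[i]; cp <- C[circ(i + 1L, n)]
  denom <- cm - 2 * c0 + cp
  frac <- if (denom != 0) 0.5 * (cm - cp) / denom else 0
  s <- (i - 1) + frac
  s <- ((s + n / 2) %% n) - n / 2           # signed, in (-n/2, n/2]
  (s / n) / dt
}

#' Accumulated wave speed along a trajectory
#'
#' Sums the signed displacement between consecutive snapshots (each assumed
#' below half a domain length) and divides by the elapsed time, removing the
#' mod-1 ambiguity of a single long-baseline measurement.
#'
#' @param fields list of [field1d()] snapshots with time stamps.
#' @export
track_wave_speed <- function(fields) {
  stopifnot(length(fields) >= 2)
  disp <- 0; tt <- 0
  for (i in seq_len(length(fields) - 1L)) {
    dt <- fields[[i + 1]]$t - fields[[i]]$t
    v <- wave_speed(fields[[i]], fields[[i + 1]], dt)
    if (is.na(v)) return(NA_real_)
    disp <- disp + v * dt
    tt <- tt + dt
  }
  disp / tt
}

#' Summary statistics of a pattern snapshot
#'
#' @param field SPP density, a [field1d()].
#' @param rho_f optional obstacle density [field1d()]; its positivity is the
#'   model-validity indicator.
#' @param prominence passed to [count_peaks()].
#' @return Object of class `pattern_summary`.
#' @export
pattern_summary <- function(field, rho_f = NULL, prominence = 0.2) {
  pk <- count_peaks(field, prominence)
  structure(list(n_peaks = pk$n_peaks, peak_positions = pk$positions,
                 min_density = min(field$values),
                 max_density = max(field$values),
                 rho_f_validity = if (is.null(rho_f)) NA else
                   min(rho_f$values) > 0),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("<pattern_summary> %d peak(s); density range [%.4g, %.4g]; rho_f valid: %s\n",
              x$n_peaks, x$min_density, x$max_density, x$rho_f_validity))
  invisible(x)
}
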