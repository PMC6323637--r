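# Continuous Morlet wavelet machinery (omega0 = 6) with Grinsted-style
# smoothing: time smoothing by a Gaussian of width equal to the scale,
# scale smoothing by a boxcar of ~0.6 octaves. The coherence is the
# smoothed cross-spectrum magnitude squared over the product of smoothed
# autospectra, averaged over the requested frequency band outside the cone
# of influence.

.omega0 <- 6
.fourier_factor <- 4 * pi / (.omega0 + sqrt(2 + .omega0^2))

.morlet_scales <- function(dt, band, dj = 1 / 12) {
  s_min <- 2 * dt
  s_max <- (1 / (.fourier_factor * band[1L])) * 2^(4 * dj)  # margin for scale smoothing
  if (s_max < s_min) {
    return(list(scales = numeric(0), freqs = numeric(0), dj = dj))
  }
  J <- ceiling(log2(s_max / s_min) / dj)
  scales <- s_min * 2^(dj * (0:J))
  list(scales = scales, freqs = 1 / (.fourier_factor * scales), dj = dj)
}

# FFT-based CWT; returns n_scales x n_timepoints complex matrix
.cwt_morlet <- function(x, dt, scales) {
  N <- length(x)
  x <- x - mean(x)
  Np <- 2^ceiling(log2(N))
  if (Np < 2L * N) Np <- 2L * Np  # pad to suppress wrap-around
  xpad <- c(x, rep(0, Np - N))
  xhat <- stats::fft(xpad)
  k <- 0:(Np - 1)
  omega <- 2 * pi * ifelse(k <= Np / 2, k, k - Np) / (Np * dt)
  W <- matrix(0 + 0i, length(scales), N)
  for (u in seq_along(scales)) {
    s <- scales[u]
    psi <- ifelse(omega > 0,
                  pi^(-1 / 4) * sqrt(2 * pi * s / dt) * exp(-(s * omega - .omega0)^2 / 2),
                  0)
    w <- stats::fft(xhat * psi, inverse = TRUE) / Np
    W[u, ] <- w[seq_len(N)]
  }
  W
}

# time smoothing: per-scale convolution with a unit-sum Gaussian of s.d.
# equal to the scale (zero-padded at the edges); FFT-based linear convolution
.smooth_time <- function(field, dt, scales) {
  N <- ncol(field)
  out <- field
  for (u in seq_along(scales)) {
    s <- scales[u]
    h <- min(N - 1L, ceiling(4 * s / dt))
    g <- exp(-(((-h):h) * dt)^2 / (2 * s^2))
    g <- g / sum(g)
    L <- 2^ceiling(log2(N + 2 * h))
    kern <- numeric(L)
    kern[1:(h + 1L)] <- g[(h + 1L):(2L * h + 1L)]   # center + right tail
    kern[(L - h + 1L):L] <- g[1:h]                  # left tail wraps
    padded <- c(field[u, ], rep(0, L - N))
    sm <- stats::fft(stats::fft(padded) * stats::fft(kern), inverse = TRUE) / L
    out[u, ] <- if (is.complex(field)) sm[seq_len(N)] else Re(sm[seq_len(N)])
  }
  out
}

# scale smoothing: running mean over +/- 3 scale bins (7 bins ~ 0.6 octaves
# at dj = 1/12), truncated and renormalized at the ends
.smooth_scale <- function(field, hw = 3L) {
  ns <- nrow(field)
  out <- field
  for (u in seq_len(ns)) {
    win <- max(1L, u - hw):min(ns, u + hw)
    out[u, ] <- colMeans(field[win, , drop = FALSE])
  }
  out
}

.smooth_field <- function(field, dt, scales) {
  .smooth_scale(.smooth_time(field, dt, scales))
}

# mask of (scale, time) cells outside the cone of influence (e-folding
# distance sqrt(2) * scale from either edge)
.coi_mask <- function(N, dt, scales) {
  dist <- pmin(seq_len(N) - 1L, N - seq_len(N)) * dt
  outer(scales, dist, function(s, d) sqrt(2) * s <= d)
}

.check_band <- function(band, dt) {
  nyq <- 1 / (2 * dt)
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L] ||
      band[2L] > nyq) {
    stop("`band` must be an increasing interval inside (0, ", nyq,
         " Hz] (the Nyquist frequency at sampling interval ", dt, " s)")
  }
}

# full coherence field machinery shared by wavelet_coherence and
# connectome_from_timeseries
.coherence_prep <- function(N, dt, band) {
  .check_band(band, dt)
  if (N < 32L) stop("time series must have at least 32 timepoints")
  sc <- .morlet_scales(dt, band)
  in_band <- sc$freqs >= band[1L] & sc$freqs <= band[2L]
  if (!any(in_band)) {
    min_len <- ceiling(2 * sqrt(2) / (.fourier_factor * band[1L] * dt))
    stop("no wavelet scale falls inside the band after discretization; ",
         "the series must have at least ~", min_len, " timepoints for this band")
  }
  mask <- .coi_mask(N, dt, sc$scales)
  use <- mask & in_band
  if (!any(use)) {
    min_len <- ceiling(2 * sqrt(2) / (.fourier_factor * band[1L] * dt)) + 1L
    stop("every in-band point lies inside the cone of influence; ",
         "series of at least ~", min_len, " timepoints are needed")
  }
  c(sc, list(use = use))
}

#' Band-averaged wavelet coherence of two time series
#'
#' Magnitude-squared wavelet coherence from the continuous Morlet transform
#' (\eqn{\omega_0 = 6}): the smoothed cross-spectrum magnitude squared over
#' the product of the smoothed autospectra at each (scale, time) cell,
#' averaged over cells whose equivalent Fourier frequency lies in `band`
#' and which fall outside the cone of influence. Values lie in [0, 1]; the
#' estimate is invariant to affine rescaling of either series.
#'
#' @param x,y Numeric time series of equal length (>= 32 points).
#' @param sampling_interval Sampling interval in seconds (the TR).
#' @param band Frequency interval in Hz, inside (0, Nyquist]; default
#'   0.01-0.08 Hz.
#' @return A single coherence value in [0, 1].
#' @export
wavelet_coherence <- function(x, y, sampling_interval = 3,
                              band = c(0.01, 0.08)) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  N <- length(x)
  dt <- sampling_interval
  prep <- .coherence_prep(N, dt, band)
  Wx <- .cwt_morlet(x, dt, prep$scales)
  Wy <- .cwt_morlet(y, dt, prep$scales)
  Sx <- Re(.smooth_field(abs(Wx)^2 / prep$scales, dt, prep$scales))
  Sy <- Re(.smooth_field(abs(Wy)^2 / prep$scales, dt, prep$scales))
  Sxy <- .smooth_field(Wx * Conj(Wy) / prep$scales, dt, prep$scales)
  R2 <- abs(Sxy)^2 / pmax(Sx * Sy, .Machine$double.xmin)
  R2 <- pmin(pmax(R2, 0), 1)
  mean(R2[prep$use])
}

#' Connectome of pairwise wavelet coherences
#'
#' Applies [wavelet_coherence()] to every unordered pair of regional time
#' series, reusing each region's wavelet transform and smoothed
#' autospectrum across pairs.
#'
#' @param values Numeric matrix, regions x timepoints.
#' @param sampling_interval Sampling interval in seconds.
#' @param band Frequency band in Hz.
#' @return A symmetric `n_regions` square matrix of coherences with zero
#'   diagonal, of class `subject_connectome`.
#' @export
connectome_from_timeseries <- function(values, sampling_interval = 3,
                                       band = c(0.01, 0.08)) {
  if (!is.matrix(values) || nrow(values) < 2L) {
    stop("`values` must be a regions x timepoints matrix with >= 2 regions")
  }
  if (anyNA(values)) stop("missing values are not allowed")
  n <- nrow(values)
  N <- ncol(values)
  dt <- sampling_interval
  prep <- .coherence_prep(N, dt, band)
  Ws <- lapply(seq_len(n), function(r) .cwt_morlet(values[r, ], dt, prep$scales))
  Ss <- lapply(Ws, function(W) {
    Re(.smooth_field(abs(W)^2 / prep$scales, dt, prep$scales))
  })
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      Sxy <- .smooth_field(Ws[[i]] * Conj(Ws[[j]]) / prep$scales, dt, prep$scales)
      R2 <- abs(Sxy)^2 / pmax(Ss[[i]] * Ss[[j]], .Machine$double.xmin)
      R2 <- pmin(pmax(R2, 0), 1)
      out[i, j] <- out[j, i] <- mean(R2[prep$use])
    }
  }
  rn <- rownames(values)
  if (!is.null(rn)) dimnames(out) <- list(rn, rn)
  structure(out, class = c("subject_connectome", "matrix"))
}

#' Generate a pair of series with controlled band-limited coherence
#'
#' Returns the band-limited pair `x = bandpass(white noise)` and
#' `y = a * x + sqrt(1 - a^2) * bandpass(independent noise)`, all band
#' components normalized to unit variance, with `a = sqrt(target)` so that
#' the theoretical in-band magnitude-squared coherence equals
#' `target_coherence`. The measured wavelet coherence approaches the target
#' up to the smoothing-induced bias at low targets.
#'
#' @param target_coherence Desired in-band coherence in [0, 1].
#' @param n_timepoints Series length.
#' @param band Frequency band in Hz (inside the Nyquist interval).
#' @param sampling_interval Sampling interval in seconds.
#' @param seed Integer seed; fixed seeds give identical output.
#' @return A list with numeric vectors `x` and `y`.
#' @export
generate_coherent_pair <- function(target_coherence, n_timepoints,
                                   band = c(0.01, 0.08),
                                   sampling_interval = 3, seed = 1L) {
  if (target_coherence < 0 || target_coherence > 1) {
    stop("`target_coherence` must lie in [0, 1]")
  }
  dt <- sampling_interval
  .check_band(band, dt)
  N <- n_timepoints
  if (N < 32L) stop("`n_timepoints` must be at least 32")
  set.seed(seed)
  bandpass <- function(z) {
    zh <- stats::fft(z)
    f <- (0:(N - 1)) / (N * dt)
    f <- pmin(f, 1 / dt - f)  # two-sided frequency magnitude
    zh[f < band[1L] | f > band[2L]] <- 0
    out <- Re(stats::fft(zh, inverse = TRUE) / N)
    out / stats::sd(out)
  }
  x <- bandpass(stats::rnorm(N))
  nz <- bandpass(stats::rnorm(N))
  a <- sqrt(target_coherence)
  y <- a * x + sqrt(1 - a^2) * nz
  list(x = x, y = y)
}
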