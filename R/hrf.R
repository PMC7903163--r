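#' Lag grid for HRF waveforms
#'
#' The hemodynamic response function (HRF) is sampled on a regular grid of
#' lags spanning `[-t_pre, t_post]` seconds at `dt` seconds per sample
#' (normally the fMRI repetition time, since the shared temporal mode of the
#' factorization is TR-sampled). The acausal part (`t_pre > 0`) allows BOLD
#' changes that precede the EEG correlate of the neural event, which have
#' repeatedly been observed around epileptogenic tissue.
#'
#' @param t_pre seconds of acausal support (default 10).
#' @param t_post seconds of causal support (default 22).
#' @param dt seconds per sample (the TR).
#' @return object of class `lag_grid` with fields `lags` (seconds, from
#'   `-t_pre` to `t_post`), `t` (seconds measured from the grid origin),
#'   `dt`, `n_pre` (number of negative-lag samples) and `n_lags`.
#' @export
lag_grid <- function(t_pre = 10, t_post = 22, dt = 2.2) {
  stopifnot(t_pre >= 0, t_post >= 0, dt > 0)
  n_pre <- as.integer(round(t_pre / dt))
  n_post <- as.integer(round(t_post / dt))
  n_lags <- n_pre + n_post + 1L
  lags <- (seq_len(n_lags) - 1L - n_pre) * dt
  structure(
    list(lags = lags, t = (seq_len(n_lags) - 1L) * dt, dt = dt,
         n_pre = n_pre, n_lags = n_lags),
    class = "lag_grid"
  )
}

#' Double-gamma HRF waveform from a five-parameter set
#'
#' Evaluates the difference of two gamma densities
#' \deqn{f(t;\theta) = \frac{\theta_2^{\theta_1}}{\Gamma(\theta_1)}
#'   t^{\theta_1-1} e^{-\theta_2 t} - \theta_5
#'   \frac{\theta_4^{\theta_3}}{\Gamma(\theta_3)} t^{\theta_3-1}
#'   e^{-\theta_4 t}}
#' on the lag grid. Time `t` is measured from the grid origin (the start of
#' the acausal support), so a gamma mode smaller than `t_pre` yields a
#' waveform whose main peak lies at a negative lag: an acausal HRF. The
#' first gamma term models the main response lobe, the second the
#' undershoot, and `theta[5]` their amplitude ratio.
#'
#' @param theta numeric length 5: two (shape, rate) pairs (all > 0) and the
#'   undershoot ratio (>= 0).
#' @param grid a [lag_grid()].
#' @return numeric waveform of length `grid$n_lags`.
#' @export
hrf_from_params <- function(theta, grid) {
  stopifnot(length(theta) == 5L, inherits(grid, "lag_grid"))
  if (any(!is.finite(theta)) || any(theta[1:4] <= 0) || theta[5] < 0) {
    stop("invalid HRF parameters: theta[1:4] must be > 0 and theta[5] >= 0")
  }
  w <- stats::dgamma(grid$t, shape = theta[1], rate = theta[2]) -
    theta[5] * stats::dgamma(grid$t, shape = theta[3], rate = theta[4])
  if (any(!is.finite(w))) stop("HRF waveform not finite on the grid")
  w
}

#' Toeplitz convolution operator
#'
#' Wraps an HRF kernel sampled on a lag grid as a linear operator on
#' TR-sampled time series: applying the operator equals the full discrete
#' convolution of the kernel with the series, advanced by `offset` samples
#' (the number of acausal kernel samples) and truncated to the series
#' length. With `offset = 0` this is the usual causal (lower-triangular
#' Toeplitz) convolution; `offset > 0` adds super-diagonals and realizes
#' acausal hemodynamic coupling.
#'
#' @param kernel numeric kernel (HRF samples, first sample = most acausal lag).
#' @param offset integer sample advance (typically `grid$n_pre`).
#' @param length output/input series length `Is`.
#' @return object of class `toeplitz_op`.
#' @export
toeplitz_op <- function(kernel, offset, length) {
  stopifnot(length >= 1, offset >= 0, offset < base::length(kernel) + length)
  structure(list(kernel = as.numeric(kernel), offset = as.integer(offset),
                 length = as.integer(length)),
            class = "toeplitz_op")
}

#' Apply a Toeplitz convolution operator
#'
#' `toeplitz_apply(op, s)` returns the first `op$length` samples of
#' `conv(kernel, s)` advanced by `op$offset` samples; it is linear in both
#' the kernel and the series. `toeplitz_apply_t` applies the transpose
#' (cross-correlation), as needed by gradient computations.
#'
#' @param op a [toeplitz_op()].
#' @param s numeric series of length `op$length` (or a matrix whose columns
#'   are such series).
#' @return filtered series with the same shape as `s`.
#' @export
toeplitz_apply <- function(op, s) {
  if (is.matrix(s)) return(apply_conv_mat(op$kernel, op$offset, s))
  apply_conv_mat(op$kernel, op$offset, matrix(s, ncol = 1L))[, 1L]
}

#' @rdname toeplitz_apply
#' @export
toeplitz_apply_t <- function(op, s) {
  m <- base::length(op$kernel)
  # H^T y with H[u, t] = kernel[u - t + 1 + offset]
  was_vec <- !is.matrix(s)
  if (was_vec) s <- matrix(s, ncol = 1L)
  n <- nrow(s)
  stopifnot(n == op$length)
  out <- matrix(0, n, ncol(s))
  for (j in seq_len(m)) {
    sh <- j - 1L - op$offset        # y index = t + sh
    t_lo <- max(1L, 1L - sh); t_hi <- min(n, n - sh)
    if (t_lo > t_hi) next
    out[t_lo:t_hi, ] <- out[t_lo:t_hi, , drop = FALSE] +
      op$kernel[j] * s[(t_lo + sh):(t_hi + sh), , drop = FALSE]
  }
  if (was_vec) out[, 1L] else out
}

# shared kernel-sliding convolution on the columns of a matrix
apply_conv_mat <- function(kernel, offset, S) {
  n <- nrow(S)
  out <- matrix(0, n, ncol(S))
  for (j in seq_along(kernel)) {
    sh <- j - 1L - offset           # output index = s index + sh
    o_lo <- max(1L, 1L + sh); o_hi <- min(n, n + sh)
    if (o_lo > o_hi) next
    out[o_lo:o_hi, ] <- out[o_lo:o_hi, , drop = FALSE] +
      kernel[j] * S[(o_lo - sh):(o_hi - sh), , drop = FALSE]
  }
  out
}

#' Materialize the Toeplitz matrix of a convolution operator
#'
#' Mostly for testing and inspection; `toeplitz_apply` never forms this
#' matrix.
#'
#' @param op a [toeplitz_op()].
#' @return `op$length` x `op$length` numeric matrix `H` with
#'   `H[u, t] = kernel[u - t + 1 + offset]`.
#' @export
toeplitz_matrix <- function(op) {
  n <- op$length
  m <- base::length(op$kernel)
  H <- matrix(0, n, n)
  for (u in seq_len(n)) for (t in seq_len(n)) {
    j <- u - t + 1L + op$offset
    if (j >= 1L && j <= m) H[u, t] <- op$kernel[j]
  }
  H
}

#' HRF basis: K parametrized waveforms on a shared lag grid
#'
#' @param theta list of K five-parameter sets (see [hrf_from_params()]).
#' @param grid a [lag_grid()].
#' @param normalize if `TRUE`, each waveform is scaled to unit Euclidean
#'   norm and the scales are returned in `$scale` (so that coefficient
#'   matrices can absorb them); the raw parametric amplitude is kept by
#'   default, as during optimization the gamma-density parametrization
#'   already fixes the scale.
#' @return object of class `hrf_basis` with `waveforms` (K x n_lags),
#'   `params`, `grid`, `scale`.
#' @export
hrf_basis <- function(theta, grid, normalize = FALSE) {
  stopifnot(is.list(theta), base::length(theta) >= 1L)
  W <- t(vapply(theta, hrf_from_params, numeric(grid$n_lags), grid = grid))
  scl <- rep(1, nrow(W))
  if (normalize) {
    nrm <- sqrt(rowSums(W^2))
    nrm[nrm < .Machine$double.eps] <- 1
    W <- W / nrm
    scl <- nrm
  }
  structure(list(waveforms = W, params = theta, grid = grid, scale = scl),
            class = "hrf_basis")
}

#' Compose an ROI-specific HRF from basis coefficients
#'
#' The HRF of region `iv` is the coefficient-weighted sum of the K basis
#' waveforms; in operator form the region's Toeplitz matrix satisfies
#' `H_iv s = sum_k b[k] * (H_k s)` (linearity, checked in the tests).
#'
#' @param basis an [hrf_basis()].
#' @param b numeric vector of K coefficients.
#' @return numeric waveform on `basis$grid`.
#' @export
roi_hrf <- function(basis, b) {
  stopifnot(base::length(b) == nrow(basis$waveforms), all(is.finite(b)))
  as.numeric(crossprod(basis$waveforms, b))
}

#' Lag (seconds) of the main lobe of an HRF waveform
#'
#' The main lobe is the largest-magnitude extremum; its (signed) lag is the
#' quantity compared when assessing HRF peak-latency recovery.
#'
#' @param w waveform on `grid`.
#' @param grid a [lag_grid()].
#' @return scalar lag in seconds.
#' @export
hrf_peak_lag <- function(w, grid) {
  grid$lags[which.max(abs(w))]
}

#' Default initial HRF parameter sets
#'
#' Double-gamma shapes whose main peaks are spread over the causal and
#' acausal support of the lag grid: a canonical waveform peaking at +5 s
#' lag (parameters shifted by `t_pre` under the grid-origin time
#' convention), an acausal waveform peaking at -5 s (the unshifted
#' canonical set, whose mode then precedes lag zero), and a delayed causal
#' waveform peaking at +7 s. Spanning both regimes matters because the
#' model's purpose includes detecting BOLD responses that precede the EEG
#' correlate; a purely causal initialization leaves the acausal basin
#' unexplored. For `K > 3`, dispersed variants are appended.
#'
#' @param K number of basis functions.
#' @param t_pre acausal support of the lag grid in seconds.
#' @return list of K five-parameter sets.
#' @export
default_hrf_params <- function(K = 3, t_pre = 10) {
  shift <- function(th, t0) c(th[1] + th[2] * t0, th[2], th[3] + th[4] * t0,
                              th[4], th[5])
  canonical <- c(6, 1, 16, 1, 1 / 6)
  delayed <- c(8, 1, 16, 1, 1 / 6)
  dispersed <- c(6, 0.8, 16, 1, 1 / 6)
  sets <- list(
    shift(canonical, t_pre),                       # causal, peak +5 s
    shift(canonical, max(t_pre - 10, 0)),          # acausal, peak 5 - t_pre
    shift(delayed, t_pre)                          # causal, peak +7 s
  )
  if (K <= 3L) return(sets[seq_len(K)])
  extra <- lapply(seq_len(K - 3L), function(i) {
    th <- dispersed
    th[2] <- th[2] * (1 + 0.15 * (i - 1))
    shift(th, t_pre)
  })
  c(sets, extra)
}
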